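#' Simulation bundle
#'
#' A complete simulated patient: the input parameters, the clonal
#' phylogeny with CCFs and variant counts, and the simulated CNV and
#' SNV tables. Bundles round-trip losslessly through
#' [export_bundle()] / [import_bundle()].
#'
#' @param params A [sim_params()].
#' @param phylogeny A `clone_phylogeny`.
#' @param cnvs,snvs Variant tables from [simulate_variants()].
#' @return A `sim_bundle` object.
#' @export
sim_bundle <- function(params, phylogeny, cnvs, snvs) {
  structure(list(params = params, phylogeny = phylogeny,
                 cnvs = cnvs, snvs = snvs),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("Simulated patient: %d clones, %d time points, %d SNVs, %d CNVs\n",
              length(x$phylogeny$parents), ncol(x$phylogeny$ccf),
              nrow(x$snvs), nrow(x$cnvs)))
  invisible(x)
}

#' Simulate a complete patient
#'
#' End-to-end simulation: phylogeny with CCFs and variant counts, CNVs,
#' SNVs, optional SNV/CNV overlaps, and read-level data.
#'
#' @param params A [sim_params()]; `params$n_variants` counts SNVs and
#'   CNVs together.
#' @param n_cnvs Number of CNVs to simulate (default 0: SNVs only).
#' @param overlap `NULL` for no overlaps, or a list
#'   `list(multiplicities =, scenario =)`: the multiplicities (how many
#'   SNVs each CNV overlaps; one entry per CNV, zeros allowed) are
#'   assigned to the simulated CNVs in random order, all under the one
#'   scenario. Alternatively a ready [configure_overlap()] spec data
#'   frame referring to CNV ids `cnv1..cnvN`.
#' @return A [sim_bundle()].
#' @examples
#' b <- simulate_patient(sim_params(n_clones = 3, n_variants = 8, seed = 7))
#' b$snvs[1:3, c("id", "clone", "VAF_t1")]
#' @export
simulate_patient <- function(params, n_cnvs = 0L, overlap = NULL) {
  phy <- simulate_phylogeny(params)
  cnvs <- simulate_cnvs(phy, params, n_cnvs)
  snvs <- place_snvs(phy, cnvs, params$n_variants - nrow(cnvs))
  spec <- NULL
  if (!is.null(overlap)) {
    if (is.data.frame(overlap)) {
      spec <- overlap
    } else {
      mult <- overlap$multiplicities
      stopifnot(length(mult) <= nrow(cnvs))
      spec <- data.frame(cnv_id = sample(cnvs$id, length(mult)),
                         n_overlapping = as.integer(mult),
                         scenario = overlap$scenario,
                         stringsAsFactors = FALSE)
      spec <- spec[spec$n_overlapping > 0, , drop = FALSE]
    }
  }
  res <- configure_overlap(snvs, cnvs, spec, phy)
  snvs <- simulate_reads(res$snvs, res$cnvs, res$phylogeny, params)
  sim_bundle(params, res$phylogeny, res$cnvs, snvs)
}

fmt1 <- function(x) sprintf("%.1f", x)

#' Export a simulation bundle
#'
#' Writes a bundle to three plain-text files with deterministic field
#' order and formatting: `ccf_matrix.tsv` (clone, parent, variant
#' count, one CCF column per time point, percent with 1 decimal, no
#' germline row), `variants.tsv` (SNVs and CNVs with per-time-point
#' depths, supporting reads, and VAFs for SNVs), and `params.yaml`.
#' Exporting, re-importing, and exporting again yields byte-identical
#' files.
#'
#' @param bundle A [sim_bundle()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the files written.
#' @export
export_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  viol <- validate_phylogeny(bundle$phylogeny, bundle$params)
  if (length(viol)) {
    stop("refusing to export an inconsistent bundle:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory ", dir, call. = FALSE)
  }
  phy <- bundle$phylogeny
  ntp <- ncol(phy$ccf)

  ccf_path <- file.path(dir, "ccf_matrix.tsv")
  ccf_df <- data.frame(clone = seq_along(phy$parents),
                       parent = phy$parents,
                       n_variants = phy$variants_per_clone)
  for (t in seq_len(ntp)) ccf_df[[sprintf("CCF_t%d", t)]] <- fmt1(phy$ccf[, t])
  utils::write.table(ccf_df, ccf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  var_path <- file.path(dir, "variants.tsv")
  na2empty <- function(x) ifelse(is.na(x), "", as.character(x))
  snv <- bundle$snvs
  cnv <- bundle$cnvs
  vd <- data.frame(
    id = c(snv$id, cnv$id),
    kind = c(rep("SNV", nrow(snv)), rep("CNV", nrow(cnv))),
    chrom = c(snv$chrom, cnv$chrom),
    start = c(snv$pos, cnv$start),
    end = c(snv$pos, cnv$end),
    ref = c(snv$ref, rep("", nrow(cnv))),
    alt = c(snv$alt, rep("", nrow(cnv))),
    cnv_type = c(rep("", nrow(snv)), cnv$cnv_type),
    clone = c(snv$clone, cnv$clone),
    overlap_cnv_id = c(na2empty(snv$overlap_cnv_id), rep("", nrow(cnv))),
    scenario = c(na2empty(snv$scenario), rep("", nrow(cnv))),
    stringsAsFactors = FALSE)
  for (t in seq_len(ntp)) {
    vd[[sprintf("depth_t%d", t)]] <-
      c(snv[[sprintf("depth_t%d", t)]], rep(NA_integer_, nrow(cnv)))
    vd[[sprintf("alt_t%d", t)]] <-
      c(snv[[sprintf("alt_t%d", t)]], rep(NA_integer_, nrow(cnv)))
    vd[[sprintf("VAF_t%d", t)]] <-
      c(fmt1(snv[[sprintf("VAF_t%d", t)]]), rep("", nrow(cnv)))
  }
  for (nm in grep("^(depth|alt)_t", names(vd), value = TRUE)) {
    vd[[nm]] <- na2empty(vd[[nm]])
  }
  utils::write.table(vd, var_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  par_path <- file.path(dir, "params.yaml")
  p <- bundle$params
  plist <- list(model = p$model,
                n_timepoints = p$n_timepoints,
                n_clones = p$n_clones,
                n_variants = p$n_variants,
                detection_threshold = p$detection_threshold,
                min_clonal_distance = p$min_clonal_distance,
                mean_coverage = p$mean_coverage,
                purity = p$purity,
                cnv_types = as.list(p$cnv_types))
  if (!is.null(p$seed)) plist$seed <- p$seed
  yaml::write_yaml(plist, par_path)

  invisible(c(ccf_path, var_path, par_path))
}

#' Import a simulation bundle
#'
#' Reads the files written by [export_bundle()] back into an identical
#' in-memory [sim_bundle()], re-validating all phylogeny constraints;
#' a hand-edited export that violates a constraint (e.g. a child CCF
#' above its parent) is rejected with the validator's message.
#'
#' @param dir Directory holding `ccf_matrix.tsv`, `variants.tsv`, and
#'   `params.yaml`.
#' @return A [sim_bundle()].
#' @export
import_bundle <- function(dir) {
  need <- c("ccf_matrix.tsv", "variants.tsv", "params.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing file(s) in ", dir, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  plist <- yaml::read_yaml(file.path(dir, "params.yaml"))
  params <- sim_params(model = plist$model,
                       n_timepoints = plist$n_timepoints,
                       n_clones = plist$n_clones,
                       n_variants = plist$n_variants,
                       detection_threshold = plist$detection_threshold,
                       min_clonal_distance = plist$min_clonal_distance,
                       mean_coverage = plist$mean_coverage,
                       purity = plist$purity,
                       cnv_types = unlist(plist$cnv_types),
                       seed = plist$seed)
  ntp <- params$n_timepoints

  ccf_df <- utils::read.delim(file.path(dir, "ccf_matrix.tsv"),
                              check.names = FALSE)
  want <- c("clone", "parent", "n_variants", sprintf("CCF_t%d", seq_len(ntp)))
  if (!all(want %in% names(ccf_df))) {
    stop("ccf_matrix.tsv: missing column(s) ",
         paste(setdiff(want, names(ccf_df)), collapse = ", "), call. = FALSE)
  }
  ccf <- as.matrix(ccf_df[, sprintf("CCF_t%d", seq_len(ntp)), drop = FALSE])
  phy <- clone_phylogeny(ccf_df$parent, ccf, ccf_df$n_variants)

  vd <- utils::read.delim(file.path(dir, "variants.tsv"),
                          check.names = FALSE,
                          colClasses = c(id = "character", ref = "character",
                                         alt = "character",
                                         cnv_type = "character",
                                         overlap_cnv_id = "character",
                                         scenario = "character"))
  empty2na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  is_snv <- vd$kind == "SNV"
  snv <- data.frame(id = vd$id[is_snv], chrom = vd$chrom[is_snv],
                    pos = vd$start[is_snv], ref = vd$ref[is_snv],
                    alt = vd$alt[is_snv], clone = vd$clone[is_snv],
                    overlap_cnv_id = empty2na(vd$overlap_cnv_id[is_snv]),
                    scenario = empty2na(vd$scenario[is_snv]),
                    stringsAsFactors = FALSE)
  for (t in seq_len(ntp)) {
    snv[[sprintf("depth_t%d", t)]] <-
      as.integer(vd[[sprintf("depth_t%d", t)]][is_snv])
    snv[[sprintf("alt_t%d", t)]] <-
      as.integer(vd[[sprintf("alt_t%d", t)]][is_snv])
    snv[[sprintf("VAF_t%d", t)]] <-
      as.numeric(vd[[sprintf("VAF_t%d", t)]][is_snv])
  }
  cnv <- data.frame(id = vd$id[!is_snv], chrom = vd$chrom[!is_snv],
                    start = vd$start[!is_snv], end = vd$end[!is_snv],
                    cnv_type = vd$cnv_type[!is_snv], clone = vd$clone[!is_snv],
                    stringsAsFactors = FALSE)

  viol <- validate_phylogeny(phy, params)
  if (length(viol)) {
    stop("imported bundle violates phylogeny constraints:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  sim_bundle(params, phy, cnv, snv)
}

#' Export simulated SNVs as VCF 4.2
#'
#' Minimal VCF with one sample column per time point and `AD`
#' (reference, alternative reads) and `DP` (depth) FORMAT fields.
#'
#' @param snvs SNV table from [simulate_reads()] / [simulate_patient()].
#' @param path Output file path.
#' @param sample_prefix Prefix of the per-time-point sample names.
#' @return Invisibly, `path`.
#' @export
export_vcf <- function(snvs, path, sample_prefix = "t") {
  ntp <- length(grep("^depth_t", names(snvs)))
  ord <- order(snvs$chrom, snvs$pos)
  s <- snvs[ord, , drop = FALSE]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0(sample_prefix, seq_len(ntp))), collapse = "\t"))
  for (i in seq_len(nrow(s))) {
    cells <- vapply(seq_len(ntp), function(t) {
      dp <- s[[sprintf("depth_t%d", t)]][i]
      ad <- s[[sprintf("alt_t%d", t)]][i]
      sprintf("%d,%d:%d", dp - ad, ad, dp)
    }, character(1))
    lines <- c(lines, paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i],
                              s$alt[i], ".", "PASS", ".", "AD:DP", cells),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
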