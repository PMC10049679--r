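#' Enumerate the 88 benchmark configurations
#'
#' Builds the full grid of 88 simulated data sets used for the
#' systematic evaluation of subclonal-reconstruction tools. The
#' baseline configuration is 3 time points, 5 clones, 20 SNVs, and 300x
#' coverage under linear evolution; each group varies one aspect:
#' \itemize{
#'   \item sim01--sim10: time points 1--10 (linear);
#'   \item sim11--sim20: clones 1--10 (linear);
#'   \item sim21--sim30: SNVs 5--50 in steps of 5 (linear);
#'   \item sim31--sim40: coverage 10x--2000x (linear);
#'   \item sim41--sim52: 20 SNVs plus 6 overlapping CNVs — four
#'     scenarios of overlap (CNV first, SNV first affected, SNV first
#'     un-affected, parallel) for each of deletions, duplications, and
#'     LOH; the 6 CNVs overlap 1, 1, 1, 2, 2, and 3 SNVs (10 of the 20
#'     SNVs in total);
#'   \item sim53--sim62 / sim63--sim70: branched dependent evolution,
#'     time points 1--10 and clones 3--10;
#'   \item sim71--sim80 / sim81--sim88: branched independent evolution,
#'     time points 1--10 and clones 3--10.
#' }
#'
#' @return A data frame with one row per configuration and columns
#'   `id`, `model`, `n_timepoints`, `n_clones`, `n_snvs`,
#'   `mean_coverage`, `n_cnvs`, `cnv_type`, `scenario`.
#' @examples
#' cfg <- build_benchmark_configs()
#' nrow(cfg)   # 88
#' @export
build_benchmark_configs <- function() {
  base <- function(id, model = "linear", ntp = 3L, nc = 5L, nsnv = 20L,
                   cov = 300, ncnv = 0L, type = NA_character_,
                   scen = NA_character_) {
    data.frame(id = id, model = model, n_timepoints = ntp, n_clones = nc,
               n_snvs = nsnv, mean_coverage = cov, n_cnvs = ncnv,
               cnv_type = type, scenario = scen, stringsAsFactors = FALSE)
  }
  cfg <- rbind(
    base(sprintf("sim%02d", 1:10), ntp = 1:10),
    base(sprintf("sim%02d", 11:20), nc = 1:10),
    base(sprintf("sim%02d", 21:30), nsnv = seq(5L, 50L, by = 5L)),
    base(sprintf("sim%02d", 31:40),
         cov = c(10, 20, 50, 100, 200, 300, 500, 1000, 1500, 2000)),
    base(sprintf("sim%02d", 41:52), ncnv = 6L,
         type = rep(c("deletion", "duplication", "LOH"), each = 4L),
         scen = rep(c("cnv_first", "snv_first_affected",
                      "snv_first_unaffected", "parallel"), times = 3L)),
    base(sprintf("sim%02d", 53:62), model = "branched_dependent", ntp = 1:10),
    base(sprintf("sim%02d", 63:70), model = "branched_dependent", nc = 3:10),
    base(sprintf("sim%02d", 71:80), model = "branched_independent", ntp = 1:10),
    base(sprintf("sim%02d", 81:88), model = "branched_independent", nc = 3:10)
  )
  cfg$n_snvs <- as.integer(cfg$n_snvs)
  rownames(cfg) <- NULL
  cfg
}

# deterministic per-patient seed below 2^31, spread across configs/patients
derive_seed <- function(base_seed, config_index, patient, attempt = 0L) {
  as.integer((as.double(base_seed) + 1000003 * config_index +
                7919 * patient + 104729 * attempt) %% 2147483647)
}

# the 6 benchmark CNVs overlap 1,1,1,2,2,3 SNVs (10 of 20)
BENCHMARK_MULTIPLICITIES <- c(1L, 1L, 1L, 2L, 2L, 3L)

# parameters and overlap settings for one benchmark configuration
config_to_params <- function(cfg_row, seed = NULL) {
  sim_params(model = cfg_row$model,
             n_timepoints = cfg_row$n_timepoints,
             n_clones = cfg_row$n_clones,
             n_variants = cfg_row$n_snvs + cfg_row$n_cnvs,
             mean_coverage = cfg_row$mean_coverage,
             cnv_types = if (is.na(cfg_row$cnv_type))
               c("deletion", "duplication", "LOH") else cfg_row$cnv_type,
             seed = seed)
}

# simulate one benchmark patient, retrying with fresh derived seeds when
# a random phylogeny/CNV draw makes the overlap scenario infeasible
simulate_benchmark_patient <- function(cfg_row, base_seed, config_index,
                                       patient, max_attempts = 25L) {
  overlap <- if (cfg_row$n_cnvs > 0L) {
    list(multiplicities = BENCHMARK_MULTIPLICITIES, scenario = cfg_row$scenario)
  }
  last <- NULL
  for (attempt in seq_len(max_attempts) - 1L) {
    seed <- derive_seed(base_seed, config_index, patient, attempt)
    params <- config_to_params(cfg_row, seed = seed)
    b <- try(simulate_patient(params, n_cnvs = cfg_row$n_cnvs,
                              overlap = overlap), silent = TRUE)
    if (!inherits(b, "try-error")) return(b)
    last <- attr(b, "condition")
  }
  stop(conditionMessage(last), call. = FALSE)
}

#' Generate the benchmark corpus
#'
#' Simulates `patients` patients for every configuration and writes
#' each as a bundle directory
#' `out_dir/<config id>/patient<k>/` holding `ccf_matrix.tsv`,
#' `variants.tsv`, `params.yaml`, plus the ground truth
#' `truth_clusters.tsv` (variant id, clone) and `truth_tree.tsv`
#' (parent, child edges; germline = 0). The corpus is deterministic
#' given `base_seed`: per-patient seeds are derived from the base seed,
#' the configuration index, and the patient index. A patient whose
#' simulation fails is reported and skipped; the remaining patients are
#' still generated.
#'
#' @param configs Configurations from [build_benchmark_configs()], or a
#'   subset of its rows.
#' @param base_seed Integer seed for the whole corpus.
#' @param out_dir Output directory.
#' @param patients Patients per configuration (default 10).
#' @return Invisibly, a data frame with one row per patient: `id`,
#'   `patient`, `dir`, `ok`, `message`.
#' @export
run_benchmark <- function(configs = build_benchmark_configs(),
                          base_seed = 1L, out_dir, patients = 10L) {
  stopifnot(is.data.frame(configs), nrow(configs) >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create directory ", out_dir, call. = FALSE)
  }
  all_cfg <- build_benchmark_configs()
  res <- vector("list", nrow(configs) * patients)
  k <- 0L
  for (r in seq_len(nrow(configs))) {
    cfg_row <- configs[r, ]
    config_index <- match(cfg_row$id, all_cfg$id)
    if (is.na(config_index)) config_index <- r
    for (pt in seq_len(patients)) {
      k <- k + 1L
      pdir <- file.path(out_dir, cfg_row$id, sprintf("patient%02d", pt))
      out <- list(id = cfg_row$id, patient = pt, dir = pdir,
                  ok = TRUE, message = "")
      b <- try(simulate_benchmark_patient(cfg_row, base_seed, config_index, pt),
               silent = TRUE)
      if (inherits(b, "try-error")) {
        out$ok <- FALSE
        out$message <- sprintf("%s patient %d: %s", cfg_row$id, pt,
                               conditionMessage(attr(b, "condition")))
        warning(out$message, call. = FALSE)
      } else {
        export_bundle(b, pdir)
        utils::write.table(truth_clustering(b$snvs, b$cnvs),
                           file.path(pdir, "truth_clusters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        edges <- data.frame(parent = b$phylogeny$parents,
                            child = seq_along(b$phylogeny$parents))
        utils::write.table(edges, file.path(pdir, "truth_tree.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      res[[k]] <- out
    }
  }
  invisible(do.call(rbind, lapply(res, as.data.frame)))
}
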