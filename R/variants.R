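# GRCh37 autosome lengths (bp), chromosomes 1-22
GRCH37_LENGTHS <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
   59128983,  63025520,  48129895,  51304566
)

CNV_TYPES <- c("deletion", "duplication", "LOH")
OVERLAP_SCENARIOS <- c("cnv_first", "snv_first_affected",
                       "snv_first_unaffected", "parallel")

# total copies at an overlapped locus, per CNV type
cnv_total_copies <- function(cnv_type) {
  switch(cnv_type, deletion = 1L, duplication = 3L, LOH = 2L,
         stop("unknown CNV type: ", cnv_type, call. = FALSE))
}

#' Genotype states at an SNV locus overlapped by a CNV
#'
#' For a given CNV type and scenario of overlap, returns the cell
#' populations present at the SNV locus and their genotype, as mutated
#' copies `m` out of total copies `t` (normal cells always contribute
#' `m = 0, t = 2`). The scenario encodes the order in which the two
#' events were acquired: `cnv_first` (the SNV arose on the rearranged
#' background), `snv_first_affected` / `snv_first_unaffected` (the CNV
#' hit the mutated or the wild-type allele of a pre-existing SNV), or
#' `parallel` (the SNV and the CNV sit in disjoint cell populations).
#'
#' @param cnv_type One of `"deletion"`, `"duplication"`, `"LOH"`.
#' @param scenario One of `"cnv_first"`, `"snv_first_affected"`,
#'   `"snv_first_unaffected"`, `"parallel"`.
#' @return A data frame with one row per tumor cell population
#'   (`snv_only`, `snv_cnv`, `cnv_only` as applicable) and columns
#'   `population`, `m`, `t`, `genotype` (A = reference allele,
#'   B = variant allele).
#' @examples
#' genotype_states("LOH", "cnv_first")      # double-hit cells keep AB
#' genotype_states("deletion", "snv_first_unaffected")
#' @export
genotype_states <- function(cnv_type, scenario) {
  cnv_type <- match.arg(cnv_type, CNV_TYPES)
  scenario <- match.arg(scenario, OVERLAP_SCENARIOS)
  tc <- cnv_total_copies(cnv_type)
  geno <- function(m, t) paste0(strrep("A", t - m), strrep("B", m))
  if (scenario == "parallel") {
    df <- data.frame(population = c("snv_only", "cnv_only"),
                     m = c(1L, 0L), t = c(2L, tc),
                     stringsAsFactors = FALSE)
  } else {
    m_sc <- switch(cnv_type,
      deletion    = switch(scenario, cnv_first = 1L,
                           snv_first_affected = 0L, snv_first_unaffected = 1L),
      duplication = switch(scenario, cnv_first = 1L,
                           snv_first_affected = 2L, snv_first_unaffected = 1L),
      LOH         = switch(scenario, cnv_first = 1L,
                           snv_first_affected = 2L, snv_first_unaffected = 0L))
    if (scenario == "cnv_first") {
      df <- data.frame(population = c("snv_cnv", "cnv_only"),
                       m = c(m_sc, 0L), t = c(tc, tc),
                       stringsAsFactors = FALSE)
    } else {
      df <- data.frame(population = c("snv_only", "snv_cnv"),
                       m = c(1L, m_sc), t = c(2L, tc),
                       stringsAsFactors = FALSE)
    }
  }
  df$genotype <- mapply(geno, df$m, df$t)
  df
}

#' Expected (CNV-adjusted) variant allele frequency
#'
#' Computes the VAF expected in a sequencing experiment for an SNV,
#' optionally overlapped by a CNV, from the cumulative CCFs of the
#' involved clones. The VAF is the copy-weighted population sum
#' \deqn{VAF = 100 \cdot \frac{\sum_p f_p m_p}{\sum_p f_p t_p}}{
#'       VAF = 100 * sum(f_p m_p) / sum(f_p t_p)}
#' over all cell populations \eqn{p} at the locus, where \eqn{f_p} is
#' the population's fraction of sampled cells, and \eqn{m_p}
#' (\eqn{t_p}) its mutated (total) copies; normal and unaffected tumor
#' cells contribute \eqn{m = 0, t = 2}. Without a CNV this reduces to
#' `purity * CCF / 2`.
#'
#' Population fractions follow from cumulative CCFs and the scenario:
#' under `cnv_first` the SNV clone is a descendant (or the same clone)
#' of the CNV clone, so double-hit cells have fraction `snv_clone_ccf`
#' and CNV-only cells `cnv_clone_ccf - snv_clone_ccf`; under
#' `snv_first_*` the roles are swapped; under `parallel` the two
#' populations are disjoint, requiring
#' `snv_clone_ccf + cnv_clone_ccf <= 100`. All tumor fractions are
#' scaled by `purity`.
#'
#' @param snv_clone_ccf CCF (percent) of the clone carrying the SNV.
#'   May be a vector (e.g. one value per time point).
#' @param cnv_clone_ccf CCF (percent) of the clone carrying the
#'   overlapping CNV, or `NULL` for an SNV without overlap. Recycled
#'   against `snv_clone_ccf`.
#' @param cnv_type,scenario See [genotype_states()]; ignored without a
#'   CNV.
#' @param purity Tumor cell fraction of the sample, in \[0, 1\].
#' @return Expected VAF(s) on the percent scale.
#' @examples
#' expected_vaf(80)                             # 40: VAF = CCF / 2
#' expected_vaf(100, 50, "deletion", "snv_first_unaffected")  # 66.7
#' @export
expected_vaf <- function(snv_clone_ccf, cnv_clone_ccf = NULL,
                         cnv_type = NULL, scenario = NULL, purity = 1) {
  stopifnot(all(snv_clone_ccf >= 0), all(snv_clone_ccf <= 100),
            purity >= 0, purity <= 1)
  if (is.null(cnv_clone_ccf)) {
    return(purity * snv_clone_ccf / 2)
  }
  stopifnot(all(cnv_clone_ccf >= 0), all(cnv_clone_ccf <= 100))
  scenario <- match.arg(scenario, OVERLAP_SCENARIOS)
  cnv_type <- match.arg(cnv_type, CNV_TYPES)
  n <- max(length(snv_clone_ccf), length(cnv_clone_ccf))
  s <- rep_len(snv_clone_ccf, n)
  c_ <- rep_len(cnv_clone_ccf, n)
  tol <- 1e-8
  if (scenario == "cnv_first" && any(s > c_ + tol)) {
    stop("CCFs inconsistent with scenario 'cnv_first': the SNV clone (",
         max(s), "%) must lie within the CNV clone (", min(c_), "%)",
         call. = FALSE)
  }
  if (scenario %in% c("snv_first_affected", "snv_first_unaffected") &&
      any(c_ > s + tol)) {
    stop("CCFs inconsistent with scenario '", scenario,
         "': the CNV clone must lie within the SNV clone", call. = FALSE)
  }
  if (scenario == "parallel" && any(s + c_ > 100 + tol)) {
    stop("CCFs inconsistent with scenario 'parallel': disjoint populations ",
         "require CCFs summing to at most 100%", call. = FALSE)
  }
  gs <- genotype_states(cnv_type, scenario)
  frac <- switch(scenario,
    cnv_first = cbind(snv_cnv = s, cnv_only = c_ - s),
    parallel  = cbind(snv_only = s, cnv_only = c_),
    cbind(snv_only = s - c_, snv_cnv = c_))   # snv_first_*
  frac <- frac[, gs$population, drop = FALSE] * purity / 100
  rest <- pmax(1 - rowSums(frac), 0)
  num <- as.vector(frac %*% gs$m)
  den <- as.vector(frac %*% gs$t) + 2 * rest
  ifelse(den > 0, 100 * num / den, 0)
}

#' Simulate copy number variants on a phylogeny
#'
#' Draws `n_cnvs` CNVs at random genomic locations (autosomes 1--22,
#' GRCh37 coordinates, lengths uniform on 1--10,000 bp). Every CNV type
#' selected in `params$cnv_types` occurs at least once; the types of
#' the remaining CNVs are uniform. Clones are assigned uniformly at
#' random, subject to each clone's variant budget
#' (`phylo$variants_per_clone`).
#'
#' @param phylo A `clone_phylogeny` with variant counts assigned.
#' @param params A [sim_params()] object.
#' @param n_cnvs Number of CNVs; must be at least the number of selected
#'   CNV types and at most `params$n_variants - 0` within clone budgets.
#' @return A data frame with columns `id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `clone` (empty if `n_cnvs` is 0).
#' @export
simulate_cnvs <- function(phylo, params, n_cnvs) {
  n_cnvs <- as.integer(n_cnvs)
  empty <- data.frame(id = character(0), chrom = integer(0),
                      start = integer(0), end = integer(0),
                      cnv_type = character(0), clone = integer(0),
                      stringsAsFactors = FALSE)
  if (n_cnvs == 0L) return(empty)
  types_sel <- params$cnv_types
  if (n_cnvs < length(types_sel)) {
    stop("n_cnvs (", n_cnvs, ") is smaller than the number of selected CNV types (",
         length(types_sel), "); each type must occur at least once", call. = FALSE)
  }
  if (n_cnvs > params$n_variants) {
    stop("n_cnvs exceeds the total variant budget", call. = FALSE)
  }
  types <- c(types_sel,
             if (n_cnvs > length(types_sel))
               sample(types_sel, n_cnvs - length(types_sel), replace = TRUE))
  types <- sample(types)   # shuffle so the forced copies sit anywhere

  budget <- phylo$variants_per_clone
  assigned <- integer(length(budget))
  clones <- integer(n_cnvs)
  for (k in seq_len(n_cnvs)) {
    open <- which(assigned < budget)
    if (!length(open)) stop("clone variant budgets exhausted while placing CNVs",
                            call. = FALSE)
    clones[k] <- if (length(open) == 1L) open else sample(open, 1L)
    assigned[clones[k]] <- assigned[clones[k]] + 1L
  }

  chrom <- sample.int(22L, n_cnvs, replace = TRUE)
  len <- sample.int(10000L, n_cnvs, replace = TRUE)
  start <- vapply(seq_len(n_cnvs), function(k) {
    sample.int(GRCH37_LENGTHS[chrom[k]] - len[k] + 1L, 1L)
  }, integer(1))
  data.frame(id = sprintf("cnv%d", seq_len(n_cnvs)),
             chrom = chrom, start = start, end = start + len - 1L,
             cnv_type = types, clone = clones, stringsAsFactors = FALSE)
}

# TRUE for positions falling inside any CNV interval on the same chromosome
inside_any_cnv <- function(chrom, pos, cnvs) {
  if (is.null(cnvs) || nrow(cnvs) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(k) {
    any(cnvs$chrom == chrom[k] & cnvs$start <= pos[k] & cnvs$end >= pos[k])
  }, logical(1))
}

#' Place SNVs outside all CNVs
#'
#' Draws `n_snvs` unique genomic positions (infinite-allele assumption)
#' uniformly over the GRCh37 autosomes, redrawing any SNV that falls
#' inside a simulated CNV by chance, and assigns clones so that each
#' clone's variant budget (variants per clone minus its CNVs) is met
#' exactly. Reference and alternative alleles are drawn uniformly with
#' `ref != alt`.
#'
#' @param phylo A `clone_phylogeny` with variant counts assigned.
#' @param cnvs CNV table from [simulate_cnvs()] (may be empty).
#' @param n_snvs Number of SNVs; together with `nrow(cnvs)` this must
#'   equal the phylogeny's total variant count.
#' @return A data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `clone`, `overlap_cnv_id` (`NA`), `scenario` (`NA`).
#' @export
place_snvs <- function(phylo, cnvs, n_snvs) {
  n_snvs <- as.integer(n_snvs)
  budget <- phylo$variants_per_clone
  cnv_per_clone <- tabulate(if (is.null(cnvs)) integer(0) else cnvs$clone,
                            nbins = length(budget))
  snv_budget <- budget - cnv_per_clone
  if (any(snv_budget < 0) || sum(snv_budget) != n_snvs) {
    stop("n_snvs does not match the per-clone variant budget ",
         "(variants_per_clone minus simulated CNVs)", call. = FALSE)
  }
  clone <- sample(rep.int(seq_along(budget), snv_budget))

  chrom <- integer(n_snvs); pos <- integer(n_snvs)
  fails <- 0L
  for (k in seq_len(n_snvs)) {
    repeat {
      ch <- sample.int(22L, 1L)
      po <- sample.int(GRCH37_LENGTHS[ch], 1L)
      clash <- inside_any_cnv(ch, po, cnvs) ||
        any(chrom[seq_len(k - 1L)] == ch & pos[seq_len(k - 1L)] == po)
      if (!clash) { chrom[k] <- ch; pos[k] <- po; fails <- 0L; break }
      fails <- fails + 1L
      if (fails >= 10000L) {
        stop("could not place an SNV outside the CNVs after 10,000 draws",
             call. = FALSE)
      }
    }
  }
  ref <- sample(c("A", "C", "G", "T"), n_snvs, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(id = sprintf("snv%d", seq_len(n_snvs)),
             chrom = chrom, pos = pos, ref = ref, alt = alt, clone = clone,
             overlap_cnv_id = NA_character_, scenario = NA_character_,
             stringsAsFactors = FALSE)
}

# clones eligible to carry an SNV overlapping the CNV in `cnv_clone`
# under the given scenario; parallel requires disjoint cell fractions
# (CCFs summing to <= 100 at every time point), which every pair of
# clones in different branches satisfies by construction
scenario_clone_candidates <- function(phylo, cnv_clone, scenario) {
  nc <- length(phylo$parents)
  keep <- vapply(seq_len(nc), function(d) {
    switch(scenario,
      cnv_first = d == cnv_clone || is_ancestor(phylo$parents, cnv_clone, d),
      snv_first_affected = ,
      snv_first_unaffected = d == cnv_clone ||
        is_ancestor(phylo$parents, d, cnv_clone),
      parallel = d != cnv_clone &&
        all(phylo$ccf[d, ] + phylo$ccf[cnv_clone, ] <= 100 + 1e-8))
  }, logical(1))
  which(keep)
}

#' Configure SNV/CNV overlaps
#'
#' Turns selected non-overlapping SNVs into SNVs overlapped by chosen
#' CNVs under a scenario of overlap. Each selected SNV is repositioned
#' uniformly inside its CNV's interval and its clone is reassigned
#' uniformly among the clones compatible with the scenario
#' (`cnv_first`: descendants of the CNV clone, or the CNV clone itself;
#' `snv_first_*`: ancestors of the CNV clone, or the clone itself;
#' `parallel`: clones whose cell population can be disjoint from the
#' CNV clone's, i.e. joint CCFs within 100% at every time point),
#' subject to every clone keeping at least one variant. The phylogeny's
#' per-clone variant counts are updated to the realized assignment.
#'
#' @param snvs SNV table from [place_snvs()].
#' @param cnvs CNV table from [simulate_cnvs()].
#' @param overlap_spec A data frame with columns `cnv_id`,
#'   `n_overlapping`, `scenario`: how many SNVs each listed CNV overlaps
#'   and under which scenario. An empty or `NULL` spec is a no-op.
#' @param phylo The `clone_phylogeny` the variants were simulated on.
#' @return A list with elements `snvs` (overlap fields and positions
#'   updated), `cnvs` (unchanged), and `phylogeny` (variant counts
#'   updated).
#' @export
configure_overlap <- function(snvs, cnvs, overlap_spec, phylo) {
  if (is.null(overlap_spec) || nrow(overlap_spec) == 0L) {
    return(list(snvs = snvs, cnvs = cnvs, phylogeny = phylo))
  }
  stopifnot(all(c("cnv_id", "n_overlapping", "scenario") %in% names(overlap_spec)))
  counts <- phylo$variants_per_clone
  for (r in seq_len(nrow(overlap_spec))) {
    cid <- overlap_spec$cnv_id[r]
    scen <- match.arg(overlap_spec$scenario[r], OVERLAP_SCENARIOS)
    ci <- match(cid, cnvs$id)
    if (is.na(ci)) stop("unknown CNV id: ", cid, call. = FALSE)
    cand <- scenario_clone_candidates(phylo, cnvs$clone[ci], scen)
    if (!length(cand)) {
      stop("scenario infeasible: no clone can carry an SNV overlapping ",
           cid, " under scenario '", scen, "'", call. = FALSE)
    }
    for (k in seq_len(overlap_spec$n_overlapping[r])) {
      free <- which(is.na(snvs$overlap_cnv_id))
      # the SNV's source clone must keep a variant unless it stays put
      ok_src <- vapply(free, function(s) {
        counts[snvs$clone[s]] > 1L || snvs$clone[s] %in% cand
      }, logical(1))
      free <- free[ok_src]
      if (!length(free)) {
        stop("scenario infeasible: no SNV left to overlap ", cid,
             " under scenario '", scen, "' within the clone budgets",
             call. = FALSE)
      }
      s <- if (length(free) == 1L) free else sample(free, 1L)
      dest_pool <- if (counts[snvs$clone[s]] > 1L) cand
                   else intersect(cand, snvs$clone[s])
      dest <- if (length(dest_pool) == 1L) dest_pool else sample(dest_pool, 1L)

      repeat {   # unique position inside the CNV interval
        po <- if (cnvs$start[ci] == cnvs$end[ci]) cnvs$start[ci]
              else sample(cnvs$start[ci]:cnvs$end[ci], 1L)
        if (!any(snvs$chrom == cnvs$chrom[ci] & snvs$pos == po)) break
      }
      counts[snvs$clone[s]] <- counts[snvs$clone[s]] - 1L
      counts[dest] <- counts[dest] + 1L
      snvs$clone[s] <- dest
      snvs$chrom[s] <- cnvs$chrom[ci]
      snvs$pos[s] <- po
      snvs$overlap_cnv_id[s] <- cid
      snvs$scenario[s] <- scen
    }
  }
  phylo$variants_per_clone <- counts
  list(snvs = snvs, cnvs = cnvs, phylogeny = phylo)
}

#' Expected VAF matrix for a set of SNVs
#'
#' Applies [expected_vaf()] per SNV and time point, resolving clone
#' CCFs and overlap annotations from the phylogeny and the CNV table.
#'
#' @inheritParams configure_overlap
#' @param params A [sim_params()] (supplies the purity).
#' @return Numeric matrix, SNVs in rows, time points in columns,
#'   percent scale.
#' @export
expected_vaf_matrix <- function(snvs, cnvs, phylo, params) {
  ntp <- ncol(phylo$ccf)
  out <- matrix(0, nrow = nrow(snvs), ncol = ntp,
                dimnames = list(snvs$id, colnames(phylo$ccf)))
  for (i in seq_len(nrow(snvs))) {
    s_ccf <- phylo$ccf[snvs$clone[i], ]
    if (is.na(snvs$overlap_cnv_id[i])) {
      out[i, ] <- expected_vaf(s_ccf, purity = params$purity)
    } else {
      ci <- match(snvs$overlap_cnv_id[i], cnvs$id)
      out[i, ] <- expected_vaf(s_ccf, phylo$ccf[cnvs$clone[ci], ],
                               cnv_type = cnvs$cnv_type[ci],
                               scenario = snvs$scenario[i],
                               purity = params$purity)
    }
  }
  out
}

#' Simulate read depths and observed VAFs
#'
#' Per SNV and time point, draws the read depth from a log-normal
#' distribution with `meanlog = log(mean_coverage)` and
#' `sdlog = |log(0.7)|` (about 0.357, matching empirical targeted/WES
#' coverage spread), adds standard normal noise to the expected VAF on
#' the percent scale (clamped to \[0, 100\], 1 decimal), and derives the
#' supporting reads as `round(depth * vaf / 100)`.
#'
#' @inheritParams expected_vaf_matrix
#' @return The `snvs` data frame extended with per-time-point columns
#'   `depth_t<k>`, `alt_t<k>`, `VAF_t<k>`.
#' @export
simulate_reads <- function(snvs, cnvs, phylo, params) {
  if (params$mean_coverage <= 0) stop("mean_coverage must be positive",
                                      call. = FALSE)
  evaf <- expected_vaf_matrix(snvs, cnvs, phylo, params)
  ntp <- ncol(evaf)
  n <- nrow(snvs)
  for (t in seq_len(ntp)) {
    depth <- as.integer(round(stats::rlnorm(n, meanlog = log(params$mean_coverage),
                                            sdlog = abs(log(0.7)))))
    vaf <- round(pmin(pmax(evaf[, t] + stats::rnorm(n), 0), 100), 1)
    snvs[[sprintf("depth_t%d", t)]] <- depth
    snvs[[sprintf("alt_t%d", t)]] <- as.integer(round(depth * vaf / 100))
    snvs[[sprintf("VAF_t%d", t)]] <- vaf
  }
  snvs
}

#' Simulate all variants of a patient
#'
#' Runs the full variant step on a simulated phylogeny: CNVs first,
#' then SNVs placed outside them, optional overlap configuration, and
#' read/VAF simulation. `n_cnvs + n_snvs` equals the phylogeny's total
#' variant count; by default all variants are SNVs.
#'
#' @param phylo A `clone_phylogeny` from [simulate_phylogeny()].
#' @param params The matching [sim_params()].
#' @param n_cnvs Number of CNVs to simulate (default 0).
#' @param overlap_spec Optional overlap specification passed to
#'   [configure_overlap()].
#' @return A list with `snvs`, `cnvs`, and the (possibly updated)
#'   `phylogeny`.
#' @export
simulate_variants <- function(phylo, params, n_cnvs = 0L, overlap_spec = NULL) {
  cnvs <- simulate_cnvs(phylo, params, n_cnvs)
  snvs <- place_snvs(phylo, cnvs, params$n_variants - nrow(cnvs))
  res <- configure_overlap(snvs, cnvs, overlap_spec, phylo)
  res$snvs <- simulate_reads(res$snvs, res$cnvs, res$phylogeny, params)
  res
}
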