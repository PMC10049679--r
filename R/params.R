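#' Simulation parameters
#'
#' Bundle and validate all user-facing settings of a clonal-evolution
#' simulation: the model of evolution, the dimensions of the phylogeny
#' (time points, clones, variants), the detectability constraints
#' (detection threshold, minimum clonal distance), and the sequencing
#' characteristics (mean coverage, purity, CNV types).
#'
#' CCFs (cancer cell fractions) are handled throughout on a percent scale
#' in \[0, 100\]. A clone's CCF is cumulative: it counts every cell
#' carrying the clone's variants, including all descendant clones.
#'
#' @param model Model of evolution. One of `"linear"` (every new clone
#'   develops from the most recently simulated clone),
#'   `"branched_dependent"` (branches arise from tumor clones), or
#'   `"branched_independent"` (branches arise directly from normal cells).
#' @param n_timepoints Number of samples collected over the course of
#'   disease (1--50, default 3).
#' @param n_clones Number of clones, i.e. clusters of variants (1--50,
#'   default 5).
#' @param n_variants Total number of variants (SNVs plus CNVs) split
#'   across the clones (1--200, default 20). Must be at least `n_clones`
#'   since every clone carries at least one variant.
#' @param detection_threshold Minimum CCF (percent) at which a clone is
#'   still detectable; every clone must reach it at one or more time
#'   points (0--50, default 2).
#' @param min_clonal_distance Minimum CCF difference (percent) separating
#'   any two clones at one or more time points (0--50, default 4).
#' @param mean_coverage Mean sequencing coverage in reads (default 300).
#' @param purity Fraction of sampled cells that are tumor cells, in
#'   \[0, 1\] (default 1). Normal cells dilute observed VAFs.
#' @param cnv_types Character vector, subset of
#'   `c("deletion", "duplication", "LOH")`: the CNV types available to the
#'   variant simulation.
#' @param seed Integer RNG seed threaded through all simulation steps.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(model = "linear", n_clones = 3, n_variants = 10)
#' p$n_clones
#' @export
sim_params <- function(model = c("linear", "branched_dependent", "branched_independent"),
                       n_timepoints = 3L,
                       n_clones = 5L,
                       n_variants = 20L,
                       detection_threshold = 2,
                       min_clonal_distance = 4,
                       mean_coverage = 300,
                       purity = 1,
                       cnv_types = c("deletion", "duplication", "LOH"),
                       seed = NULL) {
  model <- match.arg(model)
  p <- structure(list(
    model = model,
    n_timepoints = as.integer(n_timepoints),
    n_clones = as.integer(n_clones),
    n_variants = as.integer(n_variants),
    detection_threshold = as.numeric(detection_threshold),
    min_clonal_distance = as.numeric(min_clonal_distance),
    mean_coverage = as.numeric(mean_coverage),
    purity = as.numeric(purity),
    cnv_types = as.character(cnv_types),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_params")
  validate_params(p)
  p
}

#' Validate simulation parameters
#'
#' Checks all range and consistency constraints of a [sim_params()]
#' object; called by every operation that consumes parameters.
#'
#' @param p A `sim_params` object.
#' @return `p`, invisibly; errors on the first violated constraint.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$model %in% c("linear", "branched_dependent", "branched_independent"),
      "unknown model of evolution")
  chk(length(p$n_timepoints) == 1 && p$n_timepoints >= 1 && p$n_timepoints <= 50,
      "n_timepoints must be in [1, 50]")
  chk(length(p$n_clones) == 1 && p$n_clones >= 1 && p$n_clones <= 50,
      "n_clones must be in [1, 50]")
  chk(length(p$n_variants) == 1 && p$n_variants >= 1 && p$n_variants <= 200,
      "n_variants must be in [1, 200]")
  chk(p$n_variants >= p$n_clones,
      "n_variants must be >= n_clones (every clone carries a variant)")
  chk(p$detection_threshold >= 0 && p$detection_threshold <= 50,
      "detection_threshold must be in [0, 50] percent")
  chk(p$min_clonal_distance >= 0 && p$min_clonal_distance <= 50,
      "min_clonal_distance must be in [0, 50] percent")
  chk(p$mean_coverage > 0, "mean_coverage must be positive")
  chk(p$purity >= 0 && p$purity <= 1, "purity must be in [0, 1]")
  chk(all(p$cnv_types %in% c("deletion", "duplication", "LOH")),
      "cnv_types must be a subset of {deletion, duplication, LOH}")
  if (p$model != "linear" && p$n_clones > 1 && p$n_clones < 3) {
    stop("invalid model for n_clones: branched evolution requires at least 3 clones",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Clonal evolution simulation parameters\n")
  cat(sprintf("  model: %s | time points: %d | clones: %d | variants: %d\n",
              x$model, x$n_timepoints, x$n_clones, x$n_variants))
  cat(sprintf("  detection threshold: %g%% | min clonal distance: %g%%\n",
              x$detection_threshold, x$min_clonal_distance))
  cat(sprintf("  mean coverage: %gx | purity: %g | CNV types: %s\n",
              x$mean_coverage, x$purity, paste(x$cnv_types, collapse = ", ")))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
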