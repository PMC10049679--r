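#' @title Clonal phylogenies with CCF trajectories
#'
#' @description
#' A clonal phylogeny is a rooted tree of tumor clones (the root, id 0,
#' is the germline / normal-cell population) together with a matrix of
#' cancer cell fractions (CCFs, percent) per clone and time point, and a
#' count of variants carried by each clone. CCFs are cumulative: a
#' clone's CCF includes all of its descendant clones.
#'
#' A valid phylogeny satisfies, at every time point:
#' \itemize{
#'   \item a child clone's CCF never exceeds its parent's (the root is
#'     bounded by 100),
#'   \item the CCFs of a clone's direct children sum to at most the
#'     clone's own CCF, and the clones descending directly from the
#'     germline sum to at most 100,
#'   \item an eradicated clone never re-appears (once a CCF hits 0 it
#'     stays 0),
#'   \item every clone reaches the detection threshold at one or more
#'     time points,
#'   \item every pair of clones is separated by at least the minimum
#'     clonal distance at one or more time points.
#' }
#'
#' @param parents Integer vector, `parents[i]` is the parent clone of
#'   clone `i` (0 = germline).
#' @param ccf Numeric matrix, clones in rows, time points in columns,
#'   percent values in \[0, 100\].
#' @param variants_per_clone Integer vector of per-clone variant counts,
#'   or `NULL` if not yet assigned.
#' @return A `clone_phylogeny` object.
#' @seealso [simulate_phylogeny()], [validate_phylogeny()]
#' @export
clone_phylogeny <- function(parents, ccf, variants_per_clone = NULL) {
  parents <- as.integer(parents)
  ccf <- as.matrix(ccf)
  if (nrow(ccf) != length(parents)) {
    stop("dimension mismatch: ccf matrix has ", nrow(ccf),
         " rows but parent map has ", length(parents), " clones", call. = FALSE)
  }
  if (!is.null(variants_per_clone)) {
    variants_per_clone <- as.integer(variants_per_clone)
    if (length(variants_per_clone) != length(parents)) {
      stop("dimension mismatch: variants_per_clone has ",
           length(variants_per_clone), " entries but parent map has ",
           length(parents), " clones", call. = FALSE)
    }
  }
  rownames(ccf) <- paste0("c", seq_len(nrow(ccf)))
  colnames(ccf) <- paste0("t", seq_len(ncol(ccf)))
  structure(list(parents = parents, ccf = ccf,
                 variants_per_clone = variants_per_clone),
            class = "clone_phylogeny")
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  nc <- length(x$parents)
  cat(sprintf("Clonal phylogeny: %d clone%s, %d time point%s\n",
              nc, if (nc == 1) "" else "s",
              ncol(x$ccf), if (ncol(x$ccf) == 1) "" else "s"))
  tab <- data.frame(clone = seq_len(nc), parent = x$parents,
                    n_variants = if (is.null(x$variants_per_clone)) NA_integer_
                                 else x$variants_per_clone,
                    round(x$ccf, 1), check.names = FALSE)
  rownames(tab) <- NULL
  print(tab, row.names = FALSE)
  invisible(x)
}

# clone ids (excluding germline 0) on the path from `clone` up to the root
clone_ancestors <- function(parents, clone) {
  out <- integer(0)
  p <- parents[clone]
  while (p != 0L) {
    out <- c(out, p)
    p <- parents[p]
  }
  out
}

# TRUE iff `a` is an ancestor of `b` (germline 0 is an ancestor of all)
is_ancestor <- function(parents, a, b) {
  if (a == 0L) return(TRUE)
  a %in% clone_ancestors(parents, b)
}

# available CCF capacity under `parent` at every time point, given the
# clones already placed: parent's own CCF (100 for germline) minus the
# CCFs of its existing direct children
ccf_capacity <- function(parents, ccf, parent) {
  upper <- if (parent == 0L) rep(100, ncol(ccf)) else ccf[parent, ]
  kids <- which(parents == parent)
  if (length(kids)) upper <- upper - colSums(ccf[kids, , drop = FALSE])
  pmax(upper, 0)
}

# draw a CCF trajectory for one new clone: uniform on [0, capacity] per
# time point (1 decimal), with eradication made persistent
draw_ccf_trajectory <- function(capacity) {
  x <- round(stats::runif(length(capacity), 0, capacity), 1)
  dead <- which(x == 0)
  if (length(dead)) x[seq_along(x) >= dead[1]] <- 0
  x
}

# per-model parent choice for clone i (i >= 2); existing clones are 1..(i-1)
choose_parent <- function(model, i) {
  if (model == "linear") return(i - 1L)
  if (model == "branched_dependent") {
    if (i <= 3L) return(1L)                       # c2 linear from c1, c3 first branch of c1
    if (stats::runif(1) < 0.5) return(i - 1L)     # linear step
    return(sample.int(i - 1L, 1L))                # dependent branch, uniform parent
  }
  # branched_independent
  if (i == 2L) return(0L)                         # first independent branch
  if (stats::runif(1) < 0.5) return(i - 1L)
  0L
}

#' Simulate a random clonal phylogeny
#'
#' Generates a rooted clone tree and per-time-point CCF trajectories
#' under the constraints documented in [clone_phylogeny()], following
#' the requested model of evolution, and assigns variant counts to the
#' clones.
#'
#' The founding clone's CCFs are drawn uniformly on \[0, 100\] per time
#' point. Each subsequent clone attaches to a parent according to the
#' model (linear: always the most recently simulated clone; branched
#' dependent: a coin flip between a linear step and a branch off a
#' uniformly chosen tumor clone; branched independent: a coin flip
#' between a linear step and a new branch off the germline) and draws
#' CCFs uniformly within the remaining capacity under that parent. A
#' draw violating any constraint is repeated up to 100 times per clone;
#' if a clone cannot be placed, the whole simulation restarts with a new
#' founding clone, up to 700 restarts.
#'
#' @param params A [sim_params()] object. If `params$seed` is set the
#'   RNG is seeded, making the result reproducible.
#' @return A `clone_phylogeny` with `variants_per_clone` filled in.
#' @examples
#' p <- sim_params(model = "linear", n_clones = 3, n_variants = 6, seed = 1)
#' phy <- simulate_phylogeny(p)
#' validate_phylogeny(phy, p)  # character(0)
#' @export
simulate_phylogeny <- function(params) {
  validate_params(params)
  if (params$model != "linear" && params$n_clones < 3) {
    stop("invalid model for n_clones: branched evolution requires at least 3 clones",
         call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  nc <- params$n_clones
  ntp <- params$n_timepoints
  minth <- params$detection_threshold
  mindist <- params$min_clonal_distance

  ccf_ok <- function(x, ccf_so_far) {
    if (!any(x >= minth)) return(FALSE)
    if (nrow(ccf_so_far) > 0 && mindist > 0) {
      for (j in seq_len(nrow(ccf_so_far))) {
        if (!any(abs(x - ccf_so_far[j, ]) >= mindist)) return(FALSE)
      }
    }
    TRUE
  }

  for (restart in seq_len(700L)) {
    ccf <- matrix(numeric(0), nrow = 0, ncol = ntp)
    parents <- integer(0)

    founder <- NULL
    for (attempt in seq_len(100L)) {
      x <- draw_ccf_trajectory(rep(100, ntp))
      if (ccf_ok(x, ccf)) { founder <- x; break }
    }
    if (is.null(founder)) next
    ccf <- rbind(ccf, founder)
    parents <- 0L

    ok <- TRUE
    if (nc > 1) {
      for (i in 2:nc) {
        placed <- FALSE
        for (attempt in seq_len(100L)) {
          par_i <- choose_parent(params$model, i)
          x <- draw_ccf_trajectory(ccf_capacity(parents, ccf, par_i))
          if (ccf_ok(x, ccf)) {
            ccf <- rbind(ccf, x)
            parents <- c(parents, par_i)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
    }
    if (ok) {
      phy <- clone_phylogeny(parents, ccf,
                             assign_variant_counts(params, seeded = TRUE))
      return(phy)
    }
  }
  stop("no feasible phylogeny after 700 restarts; relax detection_threshold, ",
       "min_clonal_distance, or the number of clones", call. = FALSE)
}

#' Validate a clonal phylogeny
#'
#' Independently re-checks every structural and CCF constraint of a
#' phylogeny (see [clone_phylogeny()]) and reports all violations found,
#' naming the constraint, the clone(s) involved, and the time point.
#'
#' @param phylo A `clone_phylogeny`.
#' @param params A [sim_params()] supplying the detection threshold, the
#'   minimum clonal distance, and the expected total variant count.
#' @param tol Numeric slack for CCF comparisons (floating point only).
#' @return A character vector of violation messages; `character(0)` if
#'   the phylogeny is valid. Errors (rather than reporting) on dimension
#'   mismatches.
#' @export
validate_phylogeny <- function(phylo, params, tol = 1e-8) {
  stopifnot(inherits(phylo, "clone_phylogeny"))
  parents <- phylo$parents
  ccf <- phylo$ccf
  nc <- length(parents)
  ntp <- ncol(ccf)
  if (nrow(ccf) != nc) {
    stop("dimension mismatch between ccf matrix and parent map", call. = FALSE)
  }
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  # tree structure: every clone reaches germline 0 without cycles
  for (i in seq_len(nc)) {
    if (parents[i] != 0L && (parents[i] < 1L || parents[i] > nc)) {
      add(sprintf("structure: clone %d has unknown parent %d", i, parents[i]))
      next
    }
    seen <- integer(0)
    p <- i
    repeat {
      if (p == 0L) break
      if (p %in% seen) {
        add(sprintf("structure: clone %d lies on a cycle", i))
        break
      }
      seen <- c(seen, p)
      p <- parents[p]
    }
  }
  if (length(v)) return(v)  # CCF checks need a sane tree

  if (any(ccf < -tol) || any(ccf > 100 + tol)) {
    bad <- which(ccf < -tol | ccf > 100 + tol, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      add(sprintf("range: clone %d CCF %.1f outside [0, 100] at time point %d",
                  bad[k, 1], ccf[bad[k, 1], bad[k, 2]], bad[k, 2]))
    }
  }

  for (i in seq_len(nc)) {
    up <- if (parents[i] == 0L) rep(100, ntp) else ccf[parents[i], ]
    for (t in seq_len(ntp)) {
      if (ccf[i, t] > up[t] + tol) {
        add(sprintf("child exceeds parent: clone %d (%.1f) > parent %d (%.1f) at time point %d",
                    i, ccf[i, t], parents[i], up[t], t))
      }
    }
  }

  for (p in 0:nc) {
    kids <- which(parents == p)
    if (!length(kids)) next
    cap <- if (p == 0L) rep(100, ntp) else ccf[p, ]
    s <- colSums(ccf[kids, , drop = FALSE])
    for (t in seq_len(ntp)) {
      if (s[t] > cap[t] + tol) {
        add(sprintf("%s: clones {%s} sum to %.1f > %.1f at time point %d",
                    if (p == 0L) "independent clones exceed 100"
                    else sprintf("children sum exceeds parent %d", p),
                    paste(kids, collapse = ","), s[t], cap[t], t))
      }
    }
  }

  for (i in seq_len(nc)) {
    zero <- which(ccf[i, ] <= tol)
    if (length(zero)) {
      after <- seq_len(ntp) > zero[1]
      if (any(ccf[i, after] > tol)) {
        add(sprintf("eradicated clone re-appears: clone %d is 0 at time point %d but positive later",
                    i, zero[1]))
      }
    }
  }

  for (i in seq_len(nc)) {
    if (!any(ccf[i, ] >= params$detection_threshold - tol)) {
      add(sprintf("below detection threshold: clone %d never reaches %g%%",
                  i, params$detection_threshold))
    }
  }

  if (nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (!any(abs(ccf[i, ] - ccf[j, ]) >= params$min_clonal_distance - tol)) {
          add(sprintf("clones too close: clones %d and %d never differ by %g%%",
                      i, j, params$min_clonal_distance))
        }
      }
    }
  }

  if (!is.null(phylo$variants_per_clone)) {
    if (any(phylo$variants_per_clone < 1L)) {
      add(sprintf("variant counts: clone(s) %s carry no variant",
                  paste(which(phylo$variants_per_clone < 1L), collapse = ",")))
    }
    if (sum(phylo$variants_per_clone) != params$n_variants) {
      add(sprintf("variant counts: total %d differs from n_variants %d",
                  sum(phylo$variants_per_clone), params$n_variants))
    }
  }
  v
}

#' Assign variant counts to clones
#'
#' Every clone receives one variant; the remaining
#' `n_variants - n_clones` variants are split uniformly at random across
#' the clones.
#'
#' @param params A [sim_params()] object.
#' @param seeded Internal: set to `TRUE` when the RNG has already been
#'   seeded by the caller; otherwise `params$seed` (if any) is applied.
#' @return Integer vector of per-clone counts summing to
#'   `params$n_variants`, each at least 1.
#' @export
assign_variant_counts <- function(params, seeded = FALSE) {
  validate_params(params)
  if (!seeded && !is.null(params$seed)) set.seed(params$seed)
  nc <- params$n_clones
  counts <- rep(1L, nc)
  surplus <- params$n_variants - nc
  if (surplus > 0) {
    extra <- sample.int(nc, surplus, replace = TRUE)
    counts <- counts + tabulate(extra, nbins = nc)
  }
  counts
}

#' Edit a phylogeny on the clonal level
#'
#' Applies fine-tuning edits — changed CCFs, parental relations, variant
#' counts, added/deleted clones or time points — and returns the edited
#' phylogeny only if it still satisfies every constraint; otherwise no
#' edit is applied and the violations are raised as an error.
#'
#' @param phylo A `clone_phylogeny`.
#' @param params The [sim_params()] the phylogeny was simulated under.
#' @param ccf Optional replacement CCF matrix, or a data frame with
#'   columns `clone`, `timepoint`, `value` patching individual cells.
#' @param parents Optional integer vector of clone ids whose parent to
#'   change, named by target parent via `new_parent`.
#' @param new_parent Parent ids matching `parents`.
#' @param variants_per_clone Optional replacement variant-count vector.
#' @param add_timepoint Optional numeric vector of per-clone CCFs for a
#'   new final time point.
#' @param drop_timepoint Optional index of a time point to remove.
#' @param add_clone Optional list `list(parent =, ccf =, n_variants = 1)`
#'   appending a new clone.
#' @param drop_clone Optional clone id to remove; its children are
#'   re-attached to its parent and its variants returned to the parent
#'   (or dropped if the parent is the germline).
#' @return A list with elements `phylogeny` (the edited
#'   `clone_phylogeny`) and `params` (updated to the edited dimensions
#'   and variant total).
#' @export
edit_phylogeny <- function(phylo, params,
                           ccf = NULL, parents = NULL, new_parent = NULL,
                           variants_per_clone = NULL,
                           add_timepoint = NULL, drop_timepoint = NULL,
                           add_clone = NULL, drop_clone = NULL) {
  stopifnot(inherits(phylo, "clone_phylogeny"))
  pm <- phylo$parents
  m <- phylo$ccf
  vc <- phylo$variants_per_clone

  if (!is.null(ccf)) {
    if (is.data.frame(ccf)) {
      for (k in seq_len(nrow(ccf))) {
        m[ccf$clone[k], ccf$timepoint[k]] <- ccf$value[k]
      }
    } else {
      if (!all(dim(ccf) == dim(m))) {
        stop("replacement CCF matrix must match the phylogeny's dimensions",
             call. = FALSE)
      }
      m <- as.matrix(ccf)
    }
  }
  if (!is.null(parents)) {
    if (length(parents) != length(new_parent)) {
      stop("parents and new_parent must have equal length", call. = FALSE)
    }
    pm[parents] <- as.integer(new_parent)
  }
  if (!is.null(variants_per_clone)) vc <- as.integer(variants_per_clone)
  if (!is.null(add_timepoint)) {
    if (length(add_timepoint) != nrow(m)) {
      stop("add_timepoint must supply one CCF per clone", call. = FALSE)
    }
    m <- cbind(m, add_timepoint)
  }
  if (!is.null(drop_timepoint)) {
    if (ncol(m) <= 1) stop("cannot drop the only time point", call. = FALSE)
    m <- m[, -drop_timepoint, drop = FALSE]
  }
  if (!is.null(add_clone)) {
    m <- rbind(m, add_clone$ccf)
    pm <- c(pm, as.integer(add_clone$parent))
    vc <- c(vc, as.integer(if (is.null(add_clone$n_variants)) 1L
                           else add_clone$n_variants))
  }
  if (!is.null(drop_clone)) {
    id <- as.integer(drop_clone)
    keep <- setdiff(seq_along(pm), id)
    pm[pm == id] <- pm[id]
    if (!is.null(vc) && pm[id] != 0L) vc[pm[id]] <- vc[pm[id]] + vc[id]
    relabel <- function(x) ifelse(x > id, x - 1L, x)
    pm <- relabel(pm[keep])
    m <- m[keep, , drop = FALSE]
    if (!is.null(vc)) vc <- vc[keep]
  }

  out <- clone_phylogeny(pm, m, vc)
  new_params <- params
  new_params$n_clones <- length(pm)
  new_params$n_timepoints <- ncol(m)
  if (!is.null(vc)) new_params$n_variants <- sum(vc)
  viol <- validate_phylogeny(out, new_params)
  if (length(viol)) {
    stop("edit rejected:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  list(phylogeny = out, params = new_params)
}

#' Ground-truth clustering of a simulated patient
#'
#' The clone assignment of every simulated variant, in the two-column
#' layout used when scoring reconstruction tools with
#' [variation_of_information()].
#'
#' @param snvs,cnvs Variant tables from [simulate_variants()] (the CNV
#'   table may be `NULL`).
#' @return A data frame with columns `variant_id` and `cluster`.
#' @export
truth_clustering <- function(snvs, cnvs = NULL) {
  ids <- c(snvs$id, if (!is.null(cnvs) && nrow(cnvs)) cnvs$id)
  cl <- c(snvs$clone, if (!is.null(cnvs) && nrow(cnvs)) cnvs$clone)
  data.frame(variant_id = ids, cluster = cl, stringsAsFactors = FALSE)
}
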