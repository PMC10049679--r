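#' Variation of information between two clusterings
#'
#' Entropy-based distance between two partitions of the same variant
#' set: `VI = H(a) + H(b) - 2 I(a; b)` in nats (natural logarithm).
#' VI is a true metric on partitions: non-negative, symmetric,
#' satisfies the triangle inequality, and is 0 exactly when the two
#' clusterings agree up to relabeling. Lower values mean greater
#' similarity.
#'
#' @param a,b Cluster labels. Either bare label vectors of equal
#'   length (compared position-wise), or named vectors / two-column
#'   data frames (`variant_id`, `cluster`) matched by variant id.
#' @return The variation of information in nats (non-negative scalar).
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2 log 2
#' variation_of_information(rep(1, 4), 1:4)                # log 4
#' @export
variation_of_information <- function(a, b) {
  a <- as_clustering(a)
  b <- as_clustering(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("clusterings cover different variant sets", call. = FALSE)
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("clusterings cover different numbers of variants", call. = FALSE)
  }
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(joint[joint > 0] *
              log(joint[joint > 0] / outer(pa, pb)[joint > 0]))
  max(ent(pa) + ent(pb) - 2 * mi, 0)
}

as_clustering <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    out <- x[[2]]
    names(out) <- as.character(x[[1]])
    return(out)
  }
  x
}

#' Adjacency matrix of a clonal evolution tree
#'
#' Represents a clonal tree as a directed adjacency matrix over the
#' germline node plus all clones, with `A[i, j] = 1` when `i` is the
#' parent of `j`. Accepts a `clone_phylogeny` or a parent map / edge
#' list (germline = 0).
#'
#' @param x A `clone_phylogeny`, an integer parent vector
#'   (`x[i]` = parent of clone `i`), or a two-column matrix/data frame
#'   of `(parent, child)` edges.
#' @return A square 0/1 matrix with dimnames `"0"` (germline) and the
#'   clone ids; errors if the input contains a cycle or a non-root node
#'   with several parents.
#' @examples
#' tree_to_adjacency(c(0, 1, 1))   # c1 -> {c2, c3}
#' @export
tree_to_adjacency <- function(x) {
  if (inherits(x, "clone_phylogeny")) {
    parents <- x$parents
  } else if (is.matrix(x) || is.data.frame(x)) {
    e <- as.matrix(x)
    storage.mode(e) <- "integer"
    nodes <- sort(unique(c(e[, 1], e[, 2], 0L)))
    parents <- integer(max(nodes))
    seen <- logical(max(nodes))
    for (k in seq_len(nrow(e))) {
      ch <- e[k, 2]
      if (ch == 0L) stop("germline (node 0) cannot have a parent", call. = FALSE)
      if (seen[ch]) stop("node ", ch, " has multiple parents", call. = FALSE)
      parents[ch] <- e[k, 1]
      seen[ch] <- TRUE
    }
    if (!all(seen[nodes[nodes > 0]])) {
      stop("multiple roots: node(s) ",
           paste(nodes[nodes > 0][!seen[nodes[nodes > 0]]], collapse = ", "),
           " have no parent edge", call. = FALSE)
    }
  } else {
    parents <- as.integer(x)
  }
  n <- length(parents)
  if (n == 0L) stop("empty tree", call. = FALSE)
  # cycle check: every clone must reach the germline
  for (i in seq_len(n)) {
    p <- i; steps <- 0L
    while (p != 0L) {
      p <- parents[p]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected at node ", i, call. = FALSE)
    }
  }
  A <- matrix(0L, n + 1L, n + 1L,
              dimnames = rep(list(as.character(0:n)), 2))
  for (i in seq_len(n)) A[parents[i] + 1L, i + 1L] <- 1L
  A
}

#' Discrete spectral distance between two clonal trees
#'
#' Distance between the eigenvalue spectra of two trees' adjacency
#' matrices. Directed adjacencies are first symmetrized
#' (`A + t(A)`, clipped to 0/1) — the directed adjacency of a tree is
#' nilpotent, so only the undirected spectrum carries information.
#' Both spectra are sorted; if the trees differ in size the shorter
#' spectrum is zero-padded, so truths can be compared against under- or
#' over-clustered reconstructions. The distance is the Euclidean norm
#' of the spectral difference: 0 for isomorphic trees of equal size,
#' symmetric, and invariant under node relabeling.
#'
#' @param a,b Adjacency matrices from [tree_to_adjacency()] (or any
#'   square 0/1 matrices).
#' @param spectra Use eigenvalues of the symmetrized `"adjacency"`
#'   matrix (default) or of the unnormalized graph `"laplacian"`.
#' @return Non-negative spectral distance.
#' @examples
#' t1 <- tree_to_adjacency(c(0, 1, 2))  # chain
#' t2 <- tree_to_adjacency(c(0, 1, 1))  # star
#' discrete_spectral_distance(t1, t2)
#' @export
discrete_spectral_distance <- function(a, b,
                                       spectra = c("adjacency", "laplacian")) {
  spectra <- match.arg(spectra)
  spec <- function(A) {
    A <- as.matrix(A)
    if (!nrow(A)) stop("empty graph", call. = FALSE)
    S <- pmin(A + t(A), 1)
    M <- if (spectra == "laplacian") diag(rowSums(S)) - S else S
    sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  sa <- spec(a)
  sb <- spec(b)
  n <- max(length(sa), length(sb))
  pad <- function(s) if (length(s) < n) sort(c(s, rep(0, n - length(s)))) else s
  sqrt(sum((pad(sa) - pad(sb))^2))
}

#' Average spectral distance over reported trees
#'
#' Tools occasionally report several candidate trees; the score against
#' the truth is then the arithmetic mean of the discrete spectral
#' distance over all reported trees.
#'
#' @param truth Adjacency matrix of the true tree.
#' @param reported Non-empty list of adjacency matrices.
#' @param ... Passed to [discrete_spectral_distance()].
#' @return Mean distance.
#' @export
average_tree_distance <- function(truth, reported, ...) {
  if (!is.list(reported) || length(reported) == 0L) {
    stop("'reported' must be a non-empty list of trees", call. = FALSE)
  }
  mean(vapply(reported, discrete_spectral_distance, numeric(1),
              a = truth, ...))
}
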