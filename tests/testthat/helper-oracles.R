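# Independent oracles and small fixture builders used across the suite.

# Element-wise variation of information: VI = H(a|b) + H(b|a), summed per
# element over label co-occurrence counts. Independent of the package's
# contingency-table implementation.
vi_oracle <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n)) {
    na <- sum(a == a[i])
    nb <- sum(b == b[i])
    nab <- sum(a == a[i] & b == b[i])
    s <- s + log((na * nb) / nab^2)
  }
  s / n
}

# brute-force spectral distance on two explicit symmetric matrices
dsd_oracle <- function(sa, sb) {
  ea <- sort(eigen(sa, symmetric = TRUE)$values)
  eb <- sort(eigen(sb, symmetric = TRUE)$values)
  n <- max(length(ea), length(eb))
  pad <- function(s) sort(c(s, rep(0, n - length(s))))
  sqrt(sum((pad(ea) - pad(eb))^2))
}

# expected VAF by direct population bookkeeping, independent of the
# package's matrix formulation
vaf_oracle <- function(pops, purity = 1) {
  # pops: data.frame(f, m, t) with f in percent of tumor cells
  f <- pops$f * purity / 100
  num <- sum(f * pops$m)
  den <- sum(f * pops$t) + (1 - sum(f)) * 2
  100 * num / den
}

# hand-built valid 3-clone linear phylogeny over 3 time points
toy_phylogeny <- function() {
  clone_phylogeny(parents = c(0L, 1L, 2L),
                  ccf = rbind(c(90, 80, 70),
                              c(60, 50, 40),
                              c(30, 20, 10)),
                  variants_per_clone = c(2L, 2L, 2L))
}

toy_params <- function(...) {
  sim_params(n_clones = 3L, n_variants = 6L, ...)
}
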