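# Independent brute-force oracles, written separately from the package code
# paths they check.

# Triple-loop echo-integration over all cells of a (single-ESDU) echogram.
oracle_nasc <- function(eg, surface_offset = 10, classes = echo_classes()) {
  res <- list()
  for (cl in seq_len(nrow(classes))) {
    nm <- classes$name[cl]
    lo <- classes$sv_low[cl]
    hi <- classes$sv_high[cl]
    tot <- 0
    for (j in seq_len(ncol(eg$sv))) {
      for (i in seq_len(nrow(eg$sv))) {
        sv <- eg$sv[i, j]
        if (!is.na(sv) && eg$depths[i] >= surface_offset &&
            eg$depths[i] <= eg$bottom_depth[j] && sv >= lo && sv < hi) {
          tot <- tot + 10^(sv / 10) * eg$depth_step
        }
      }
    }
    res[[nm]] <- 4 * pi * 1852^2 * tot / ncol(eg$sv)
  }
  res
}

# Accumulation-loop weighted mean position.
oracle_barycenter <- function(lat, lon, w) {
  sl <- 0; so <- 0; sw <- 0
  for (i in seq_along(w)) {
    sl <- sl + w[i] * lat[i]
    so <- so + w[i] * lon[i]
    sw <- sw + w[i]
  }
  c(lat = sl / sw, lon = so / sw)
}

# Lexicographic permutation generation by recursion on remaining elements
# (distinct from the package's insertion-based generator).
perms_lex <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perms_lex(v[-i])))
  out
}

# Exact two-sided Spearman trend p by full enumeration of value orderings.
oracle_spearman <- function(values, times) {
  rv <- rank(values)
  rt <- rank(times)
  rho <- stats::cor(rv, rt)
  perms <- perms_lex(seq_along(values))
  rhos <- apply(perms, 1, function(p) stats::cor(rank(values[p]), rt))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Exact paired signed-rank test by enumeration of all 2^n sign assignments.
oracle_signedrank <- function(day, night) {
  d <- night - day
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  list(W = min(V, n * (n + 1) / 2 - V),
       p = min(1, 2 * min(mean(Vs <= V), mean(Vs >= V))))
}
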