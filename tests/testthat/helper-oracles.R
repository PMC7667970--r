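# Independent oracles used across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled ranks (tie-free inputs only).
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Brute-force pointwise median of normalized curves on the union grid with
# explicit zero padding beyond each curve's extent.
median_curve_bruteforce <- function(curves_list) {
  grid <- sort(unique(unlist(lapply(curves_list, function(c) c$x_um))))
  f <- sapply(curves_list, function(c) {
    m <- match(grid, c$x_um)
    ifelse(is.na(m), 0, c$f[m])
  })
  data.frame(x_um = grid, f_median = apply(as.matrix(f), 1, median))
}

# distance sampler straight from the mixture law (bypasses simulate_beads)
sample_distances <- function(model, n) {
  dd <- mucometry:::draw_depths(model, n)
  model$thickness - dd$depth
}
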