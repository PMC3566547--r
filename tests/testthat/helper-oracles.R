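# Exact-enumeration Mann-Whitney oracle: enumerates all C(n+m, n) group
# assignments of the pooled sample and computes the two-sided p the same
# way the exact distribution does (doubled smaller tail, capped at 1).
# Independent of stats::wilcox.test.
mw_exact_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# small well-separated blob dataset used across fcm tests
blob_fm <- function(n_per = 20, centers = c(0, 10), sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- unlist(lapply(centers, function(m) rnorm(n_per, m, sd)))
    y <- rnorm(n_per * length(centers), 0, sd)
  })
  feature_matrix(cbind(x = x, y = y), kinds = "continuous")
}
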