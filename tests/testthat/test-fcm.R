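test_that("membership formula matches hand-evaluated cases", {
  # distances 1 and 2, mu = 2 -> exponent 2, memberships (0.8, 0.2)
  m <- fcm_memberships(matrix(0), matrix(c(1, 2)), mu = 2)
  expect_equal(as.vector(m), c(0.8, 0.2))
  # cell on a centroid takes membership 1 there
  m0 <- fcm_memberships(matrix(0), matrix(c(0, 5)), mu = 1.5)
  expect_equal(as.vector(m0), c(1, 0))
  # equidistant from all centroids -> uniform for any mu
  for (mu in c(1.1, 2, 5)) {
    me <- fcm_memberships(matrix(c(0, 0), 1), rbind(c(1, 0), c(-1, 0),
                                                    c(0, 1)), mu = mu)
    expect_equal(as.vector(me), rep(1 / 3, 3))
  }
})

test_that("centroid update is the mu-power weighted mean", {
  # 1-D cells 0 and 1, memberships (0.8, 0.2)/(0.2, 0.8), mu = 2
  M <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  u <- fcm_centroids(matrix(c(0, 1)), M, mu = 2)
  expect_equal(as.vector(u), c(0.04 / 0.68, 0.64 / 0.68))
  # crisp memberships give per-cluster arithmetic means for any mu
  X <- matrix(c(1, 2, 10, 12), ncol = 1)
  Mc <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  for (mu in c(1.2, 2, 4))
    expect_equal(as.vector(fcm_centroids(X, Mc, mu)), c(1.5, 11))
  # uniform memberships put every centroid at the grand mean
  Mu <- matrix(1 / 3, 4, 3)
  expect_equal(as.vector(fcm_centroids(X, Mu, mu = 2)), rep(6.25, 3))
})

test_that("cost is the membership-weighted squared-distance sum", {
  # one cell at distance 1 from both centroids, memberships 0.5/0.5, mu = 2
  X <- matrix(c(0, 0), 1)
  U <- rbind(c(1, 0), c(-1, 0))
  expect_equal(fcm_cost(X, matrix(c(0.5, 0.5), 1), U, mu = 2), 0.5)
  # cells exactly on sole-membership centroids -> J = 0
  X2 <- rbind(c(1, 0), c(-1, 0))
  M2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(fcm_cost(X2, M2, U, mu = 1.5), 0)
  # doubling all distances quadruples J at fixed memberships
  M <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  j1 <- fcm_cost(X2, M, U, mu = 2)
  j2 <- fcm_cost(2 * X2, M, 2 * U, mu = 2)
  expect_equal(j2, 4 * j1)
})

test_that("fit keeps rows stochastic and the cost non-increasing", {
  ds <- generate_synthetic(synthetic_spec(G = 3, n_archetypal = 25,
                                          rng_seed = 7))
  p <- fcm_fit(ds$fm, fcm_config(mu = 1.4, rng_seed = 3, c_max = 10))
  expect_lt(max(abs(rowSums(p$memberships) - 1)), 1e-9)
  expect_lt(max(diff(p$cost_trace)), 1e-10)
  expect_gte(p$cost, 0)
  expect_true(all(p$memberships >= 0 & p$memberships <= 1))
  expect_lte(p$c_effective, 10)
})

test_that("refitting with identical seeds is bit-identical", {
  fm <- blob_fm()
  cfg <- fcm_config(mu = 1.3, rng_seed = 11, c_max = 4,
                    seed_points = c(1L, 21L))
  p1 <- fcm_fit(fm, cfg)
  p2 <- fcm_fit(fm, cfg)
  expect_identical(p1$memberships, p2$memberships)
  expect_identical(p1$centroids, p2$centroids)
  expect_identical(p1$cost, p2$cost)
})

test_that("saturated clustering drives the cost to zero", {
  # as many clusters as cells: every cell hosts its own centroid
  fm <- blob_fm(n_per = 3, centers = c(0, 20, 40))
  p <- fcm_fit(fm, fcm_config(mu = 1.2, rng_seed = 1, c_max = 9))
  expect_lt(p$cost, 1e-6)
})

test_that("permuting cells permutes membership rows; feature order is moot", {
  fm <- blob_fm()
  cfg <- fcm_config(mu = 1.3, rng_seed = 5, c_max = 3, seed_points = 1:3)
  p <- fcm_fit(fm, cfg)
  perm <- withr::with_seed(9, sample(nrow(fm$raw)))
  fmp <- feature_matrix(fm$raw[perm, ], kinds = fm$kinds)
  # seed cells follow the permutation so the initialization is the same
  cfgp <- fcm_config(mu = 1.3, rng_seed = 5, c_max = 3,
                     seed_points = match(1:3, perm))
  pp <- fcm_fit(fmp, cfgp)
  expect_equal(unname(pp$memberships), unname(p$memberships[perm, ]),
               tolerance = 1e-8)
  fmf <- feature_matrix(fm$raw[, 2:1], kinds = fm$kinds[2:1])
  pf <- fcm_fit(fmf, cfg)
  expect_equal(unname(pf$memberships), unname(p$memberships),
               tolerance = 1e-8)
})

test_that("fcm agrees with the e1071 reference on a shared initialization", {
  skip_if_not_installed("e1071")
  fm <- blob_fm(n_per = 15)
  cfg <- fcm_config(mu = 1.6, rng_seed = 2, c_max = 2)
  p <- fcm_fit(fm, cfg)
  X <- fm$standardized
  cm <- e1071::cmeans(X, centers = X[p$init_indices, , drop = FALSE],
                      m = 1.6, iter.max = 1000)
  ord <- apply(fuzzyarchetypes:::.overlap_matrix(p$memberships, cm$membership),
               1, which.max)
  expect_lt(max(abs(p$memberships - cm$membership[, ord])), 1e-3)
})

test_that("coalescence merges by transitive closure and sums memberships", {
  fm <- blob_fm()
  p <- fcm_fit(fm, fcm_config(mu = 1.3, rng_seed = 1, c_max = 2))
  # byte-identical duplicate centroids always merge, columns sum
  dup <- p
  dup$centroids <- rbind(p$centroids, p$centroids[1, ])
  dup$memberships <- cbind(p$memberships[, 1] / 2, p$memberships[, 2],
                           p$memberships[, 1] / 2)
  dup$c_effective <- 3L
  merged <- coalesce(dup, 0.001)
  expect_equal(merged$c_effective, 2L)
  expect_equal(unname(merged$memberships[, 1]),
               unname(dup$memberships[, 1] + dup$memberships[, 3]))
  expect_length(merged$coalescence_log, 1L)
  expect_equal(merged$coalescence_log[[1]], c(1L, 3L))

  # chain A-B-C with |A-B| < eps, |B-C| < eps, |A-C| > eps merges all three
  chain <- p
  chain$centroids <- matrix(c(0, 0.0008, 0.0016), 3, 1)
  chain$memberships <- matrix(1 / 3, nrow(fm$raw), 3)
  chain$c_effective <- 3L
  out <- coalesce(chain, 0.001)
  expect_equal(out$c_effective, 1L)

  # all distances above epsilon: unchanged, empty log
  keep <- coalesce(p, 1e-9)
  expect_identical(keep$memberships, p$memberships)
  expect_length(keep$coalescence_log, 0L)
})

test_that("pathological configurations raise clear errors", {
  fm <- blob_fm()
  expect_error(fcm_config(mu = 1, rng_seed = 1), "mu")
  expect_error(fcm_fit(fm, fcm_config(mu = 1.3, rng_seed = 1, c_max = 200)),
               "c_max")
  expect_error(fcm_centroids(matrix(c(0, 1)), rbind(c(1, 0), c(0, 1)),
                             mu = 2), NA)
  expect_error(fcm_centroids(matrix(c(0, 1)), rbind(c(1, 0), c(1, 0)),
                             mu = 2), "empty cluster")
})
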