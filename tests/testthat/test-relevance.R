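planted_fm <- function(seed = 1001) {
  generate_synthetic(planted_feature_spec(n_per = 75, rng_seed = seed))
}
planted_cfg <- function(seed = 1) {
  fcm_config(mu = 1.05, rng_seed = seed, c_max = 2, n_restarts = 5)
}

test_that("scrambling permutes values within columns only", {
  ds <- planted_fm()
  scr <- scramble_features(ds$fm, c("ephys_01", "ephys_03"), rng_seed = 4)
  for (f in c("ephys_01", "ephys_03")) {
    expect_equal(sort(unname(scr$raw[, f])), sort(unname(ds$fm$raw[, f])))
    expect_false(identical(scr$raw[, f], ds$fm$raw[, f]))
  }
  untouched <- setdiff(colnames(ds$fm$raw), c("ephys_01", "ephys_03"))
  expect_identical(scr$raw[, untouched], ds$fm$raw[, untouched])
  # standardized values follow the same permutation
  perm <- match(scr$raw[, "ephys_01"], ds$fm$raw[, "ephys_01"])
  expect_equal(scr$standardized[, "ephys_01"],
               ds$fm$standardized[perm, "ephys_01"], ignore_attr = TRUE)
  expect_error(scramble_features(ds$fm, "nope", 1), "unknown feature")
  # independent streams: two columns virtually never share a permutation
  big <- scramble_features(ds$fm, 1:2, rng_seed = 9)
  p1 <- match(big$raw[, 1], ds$fm$raw[, 1])
  p2 <- match(big$raw[, 2], ds$fm$raw[, 2])
  expect_false(identical(p1, p2))
})

test_that("tied values scramble to an identical column", {
  fm <- suppressWarnings(
    feature_matrix(cbind(k = c(1, 1), x = c(0, 2)), kinds = "continuous"))
  scr <- scramble_features(fm, "k", rng_seed = 3)
  expect_identical(scr$raw[, "k"], fm$raw[, "k"])
})

test_that("a constant column has exactly zero scrambling cost", {
  ds <- planted_fm()
  raw <- cbind(ds$fm$raw, konst = 5)
  fm <- suppressWarnings(
    feature_matrix(raw, kinds = rep("continuous", ncol(raw))))
  cfg <- planted_cfg()
  dc <- delta_cost(fm, "konst", cfg, R = 5, rng_seed = 11)
  expect_identical(dc$delta_j, rep(0, 5))
  expect_identical(dc$mean, 0)
  expect_equal(dc$R_effective, 5)
})

test_that("two correlated informative features rank above pure noise", {
  # both carry the same bipartition; scrambling either one leaves the other
  # anchoring the partition, so its decorrelation genuinely costs
  s <- 8 / sqrt(2) / 2
  ctr <- matrix(0, 2, 10); ctr[1, 1:2] <- s; ctr[2, 1:2] <- -s
  ds <- generate_synthetic(synthetic_spec(G = 2, F_cont = 10, F_bool = 0,
                                          centroids = ctr, n_archetypal = 30,
                                          transition_cells = list(),
                                          rng_seed = 1001))
  cfg <- fcm_config(mu = 1.349, rng_seed = 1, c_max = 2)
  rk <- rank_features(ds$fm, cfg, R = 60, rng_seed = 7)
  expect_setequal(rk$ranking$feature[1:2], c("ephys_01", "ephys_02"))
  expect_gt(min(rk$ranking$delta_j_mean[1:2]),
            max(rk$ranking$delta_j_mean[-(1:2)]) + 1)
  expect_true(all(rk$ranking$delta_j_sd >= 0))
  expect_setequal(rk$ranking$feature, ds$fm$feature_names)
})

test_that("single-feature tables produce a trivial ranking", {
  withr::with_seed(2, {
    fm <- feature_matrix(cbind(v = c(rnorm(10), rnorm(10, 6))),
                         kinds = "continuous")
  })
  rk <- rank_features(fm, fcm_config(mu = 1.2, rng_seed = 1, c_max = 2),
                      R = 5, rng_seed = 3)
  expect_equal(nrow(rk$ranking), 1L)
  expect_equal(rk$ranking$rank, 1L)
})

test_that("reduced classification is self-consistent at K = F", {
  ds <- planted_fm()
  cfg <- planted_cfg()
  res <- reduced_classification(ds$fm, colnames(ds$fm$raw),
                                K = ncol(ds$fm$raw), cfg)
  expect_equal(res$overall_matching, 100)
  expect_true(all(res$per_archetype$matching_fraction == 100))
  expect_error(reduced_classification(ds$fm, colnames(ds$fm$raw), 0, cfg),
               "between 1")
})

test_that("one planted feature suffices for the reduced classification", {
  ds <- planted_fm()
  res <- reduced_classification(ds$fm, "ephys_01", K = 1, planted_cfg())
  expect_gte(res$overall_matching, 95)
  # matching fractions ignore the labeling of reduced clusters
  expect_true(all(res$per_archetype$matching_fraction >= 90))
})

test_that("cluster matching maximizes total overlap deterministically", {
  O <- rbind(c(5, 1, 0), c(4, 3, 0))
  # greedy would take (1,1) then (2,2) for 8; optimal is (1,2)? no: optimal
  # assignment here is (1->1, 2->2) = 8 vs (1->2, 2->1) = 5; exhaustive path
  expect_equal(fuzzyarchetypes:::.assign_clusters(O), c(1L, 2L))
  O2 <- rbind(c(5, 4), c(5, 1), c(0, 0))
  m2 <- fuzzyarchetypes:::.assign_clusters(O2)
  expect_equal(m2[1:2], c(2L, 1L)) # total 9 beats greedy-first 5+1
  expect_true(is.na(m2[3]))
})
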