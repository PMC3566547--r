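# small fitted scenario shared across profiling tests
profiled_fixture <- function() {
  ds <- generate_synthetic(synthetic_spec(G = 2, F_cont = 4, F_bool = 2,
                                          n_archetypal = 15,
                                          transition_cells = list(),
                                          rng_seed = 21))
  part <- fcm_fit(ds$fm, fcm_config(mu = 1.2, rng_seed = 1, c_max = 2))
  list(ds = ds, part = part,
       prof = weighted_profile(ds$fm, part))
}

test_that("weighted statistics reduce to mean and unbiased SD under equal weights", {
  # direct check of the weighted formulas against stats::mean/sd
  wmean <- function(w, v) sum(w * v) / sum(w)
  wsd <- function(w, v) {
    m <- wmean(w, v)
    sqrt(sum(w) * sum(w * (v - m)^2) / (sum(w)^2 - sum(w^2)))
  }
  withr::with_seed(99, {
    for (i in 1:200) {
      v <- rnorm(sample(3:30, 1))
      w <- rep(runif(1, 0.1, 1), length(v))
      expect_equal(wmean(w, v), mean(v), tolerance = 1e-12)
      expect_equal(wsd(w, v), sd(v), tolerance = 1e-12)
    }
  })
})

test_that("profiles carry weighted means, symmetric ranges and occurrences", {
  fx <- profiled_fixture()
  prof <- fx$prof
  expect_equal(sum(prof$n_members), nrow(fx$ds$fm$raw))
  expect_true(all(prof$weighted_sd >= 0, na.rm = TRUE))
  expect_true(all(prof$occurrence >= 0 & prof$occurrence <= 100))
  expect_equal(prof$range_high - prof$weighted_mean,
               prof$weighted_mean - prof$range_low)
  # degenerate weight vector (1, 0, 0, ...) pins the mean on that cell
  M <- fx$part$memberships
  sp <- typicality_spectrum(fx$part)
  a <- 1L
  I <- which(sp$cells$main_type == a)
  w <- M[I, a]; w[] <- 0; w[1L] <- 1
  v <- fx$ds$fm$raw[I, 1L]
  expect_equal(sum(w * v) / sum(w), unname(v[1L]))
})

test_that("single-member and empty archetypes degrade with warnings", {
  raw <- cbind(x = c(0, 0.1, -0.1, 9), y = c(0, 0.2, -0.2, 9))
  fm <- feature_matrix(raw, kinds = "continuous")
  part <- fcm_fit(fm, fcm_config(mu = 1.2, rng_seed = 1, c_max = 2,
                                 seed_points = c(1L, 4L)))
  expect_warning(prof <- weighted_profile(fm, part), "single member")
  lone <- which(prof$n_members == 1L)
  expect_true(all(is.na(prof$weighted_sd[lone, ])))
  expect_equal(prof$weighted_mean[lone, "x"], 9, tolerance = 0.2,
               ignore_attr = TRUE)
})

test_that("Mann-Whitney p-values agree with exact enumeration", {
  # the stated closed case: disjoint triples give exact two-sided p = 0.1
  expect_equal(mw_exact_enum_p(c(1, 2, 3), c(101, 102, 103)), 0.1)
  expect_equal(wilcox.test(c(1, 2, 3), c(101, 102, 103),
                           exact = TRUE)$p.value, 0.1)
  # random tie-free samples, all group sizes up to 6
  withr::with_seed(7, {
    for (na in 2:6) for (nb in 2:6) {
      x <- rnorm(na); y <- rnorm(nb, 0.5)
      expect_equal(wilcox.test(x, y, exact = TRUE)$p.value,
                   mw_exact_enum_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("pairwise archetype comparisons choose the right test", {
  fx <- profiled_fixture()
  cont <- compare_archetypes(fx$ds$fm, fx$prof, 1, 2, "ephys_01")
  expect_equal(cont$test, "mann-whitney")
  boolcmp <- compare_archetypes(fx$ds$fm, fx$prof, 1, 2, "marker_01")
  expect_equal(boolcmp$test, "fisher")
  expect_true(cont$p_value >= 0 && cont$p_value <= 1)
  # balanced 2x2 table -> Fisher p = 1
  expect_equal(fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # identical value multisets -> no evidence of difference
  expect_gt(suppressWarnings(
    wilcox.test(c(1, 2, 3), c(1, 2, 3))$p.value), 0.9)
  all_cmp <- compare_all_archetypes(fx$ds$fm, fx$prof)
  expect_equal(nrow(all_cmp), length(fx$ds$fm$feature_names))
  expect_true(all(all_cmp$tier %in% c("", "<", "<<", "<<<")))
  holm <- compare_all_archetypes(fx$ds$fm, fx$prof, adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p_value))
})

test_that("typical-range color coding returns every covering archetype", {
  fx <- profiled_fixture()
  prof <- fx$prof
  # the weighted mean itself always falls in its own archetype's range
  for (a in 1:2)
    expect_true(a %in% feature_color_code(prof$weighted_mean[a, "ephys_01"],
                                          prof, "ephys_01"))
  # far outside every range -> empty
  expect_length(feature_color_code(1e6, prof, "ephys_01"), 0L)
  # overlapping ranges return both archetypes
  prof2 <- prof
  prof2$range_low[, 1] <- c(0, 1); prof2$range_high[, 1] <- c(2, 3)
  expect_equal(feature_color_code(1.5, prof2, 1L), c(1L, 2L))
  expect_error(feature_color_code(0, prof, "nope"), "unknown feature")
})
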