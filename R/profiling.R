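#' Membership-weighted archetype profiles
#'
#' Characterizes each archetype by weighted statistics of the raw
#' (unit-bearing) feature values of its member cells, the weights being the
#' cells' memberships toward their main type. The weighted mean is
#' `f_bar = sum w_i f_i / sum w_i` and the weighted standard deviation
#' `sigma = sqrt( sum(w) * sum w_i (f_i - f_bar)^2 / ((sum w)^2 - sum w^2) )`,
#' which reduce exactly to the ordinary sample mean and unbiased (n-1) SD
#' under equal weights. Weighting damps the contribution of atypical cells,
#' so profiles dominantly reflect archetypal members. The typical range of a
#' feature is `f_bar +/- sigma`. For boolean markers the weighted mean of the
#' 0/1 values times 100 gives an occurrence percentage; raw (unweighted)
#' proportions are also reported.
#'
#' A single-member archetype has an undefined sigma (reported `NA` with a
#' warning); an empty archetype is skipped with a warning.
#'
#' @param fm a [feature_matrix()] (raw values are profiled).
#' @param partition a `fuzzy_partition` fitted on `fm`.
#' @param spectrum optionally a precomputed [typicality_spectrum()]; derived
#'   from the partition if omitted.
#' @return an object of class `archetype_profile`: matrices `weighted_mean`,
#'   `weighted_sd`, `range_low`, `range_high` (archetypes x features),
#'   `occurrence` and `raw_occurrence` (archetypes x boolean features, %),
#'   `n_members`, `member_sets`, and feature metadata.
#' @export
weighted_profile <- function(fm, partition, spectrum = NULL) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(partition, "fuzzy_partition"))
  if (is.null(spectrum)) spectrum <- typicality_spectrum(partition)
  M <- partition$memberships
  c_star <- ncol(M)
  f <- length(fm$feature_names)
  main <- spectrum$cells$main_type

  wm <- wsd <- matrix(NA_real_, c_star, f,
                      dimnames = list(NULL, fm$feature_names))
  n_members <- integer(c_star)
  member_sets <- vector("list", c_star)
  for (a in seq_len(c_star)) {
    I <- which(main == a)
    member_sets[[a]] <- fm$cell_ids[I]
    n_members[a] <- length(I)
    if (length(I) == 0L) {
      warning(sprintf("archetype %d has no member cells; skipped", a))
      next
    }
    w <- M[I, a]
    sw <- sum(w); sw2 <- sum(w^2)
    for (j in seq_len(f)) {
      v <- fm$raw[I, j]
      wm[a, j] <- sum(w * v) / sw
      if (length(I) >= 2L)
        wsd[a, j] <- sqrt(sw * sum(w * (v - wm[a, j])^2) / (sw^2 - sw2))
    }
    if (length(I) == 1L)
      warning(sprintf(
        "archetype %d has a single member; weighted SD undefined", a))
  }

  bool_j <- which(fm$kinds == "boolean")
  occurrence <- 100 * wm[, bool_j, drop = FALSE]
  raw_occ <- matrix(NA_real_, c_star, length(bool_j),
                    dimnames = list(NULL, fm$feature_names[bool_j]))
  for (a in seq_len(c_star)) {
    I <- which(main == a)
    if (length(I))
      raw_occ[a, ] <- 100 * colMeans(fm$raw[I, bool_j, drop = FALSE])
  }

  structure(list(weighted_mean = wm, weighted_sd = wsd,
                 range_low = wm - wsd, range_high = wm + wsd,
                 occurrence = occurrence, raw_occurrence = raw_occ,
                 n_members = n_members, member_sets = member_sets,
                 feature_names = fm$feature_names, kinds = fm$kinds,
                 c_effective = c_star),
            class = "archetype_profile")
}

#' @export
print.archetype_profile <- function(x, ...) {
  cat(sprintf("archetype_profile: %d archetypes x %d features (members: %s)\n",
              x$c_effective, length(x$feature_names),
              paste(x$n_members, collapse = ", ")))
  invisible(x)
}

#' Pairwise archetype comparison for one feature
#'
#' Tests whether the raw values of a feature differ between the
#' (unweighted) member sets of two archetypes: a two-tailed Mann-Whitney U
#' test for continuous features (exact p when the smaller group has at most
#' 8 members and there are no ties, normal approximation with tie/continuity
#' correction otherwise) and a two-tailed Fisher exact test on the 2 x 2
#' count table for boolean features. Raw p-values are returned, with a
#' significance tier ("<" p < 0.05, "<<" p < 0.01, "<<<" p < 0.001) attached
#' purely for reporting.
#'
#' @param fm a [feature_matrix()].
#' @param profile an [weighted_profile()] result (supplies the member sets).
#' @param alpha,beta archetype indices to compare.
#' @param feature feature name or index.
#' @return list with `statistic`, `p_value`, `test` and `tier`.
#' @export
compare_archetypes <- function(fm, profile, alpha, beta, feature) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(profile, "archetype_profile"))
  j <- .feature_index(fm, feature)
  Ia <- match(profile$member_sets[[alpha]], fm$cell_ids)
  Ib <- match(profile$member_sets[[beta]], fm$cell_ids)
  if (length(Ia) == 0L || length(Ib) == 0L)
    stop("both member sets must be non-empty")
  xa <- fm$raw[Ia, j]; xb <- fm$raw[Ib, j]

  if (fm$kinds[j] == "continuous") {
    use_exact <- min(length(xa), length(xb)) <= 8 &&
      !any(duplicated(c(xa, xb)))
    ht <- wilcox.test(xa, xb, alternative = "two.sided", exact = use_exact,
                      correct = TRUE)
    stat <- unname(ht$statistic)
    test <- "mann-whitney"
  } else {
    tab <- matrix(c(sum(xa == 1), sum(xa == 0),
                    sum(xb == 1), sum(xb == 0)), nrow = 2)
    ht <- fisher.test(tab, alternative = "two.sided")
    stat <- unname(ht$estimate)
    test <- "fisher"
  }
  p <- ht$p.value
  tier <- if (p < 0.001) "<<<" else if (p < 0.01) "<<" else if (p < 0.05) "<"
  else ""
  list(statistic = stat, p_value = p, test = test, tier = tier)
}

#' All pairwise archetype comparisons
#'
#' Runs [compare_archetypes()] for every archetype pair and feature. No
#' multiple-testing correction is applied by default; Holm correction is
#' available behind `adjust = "holm"`.
#'
#' @inheritParams compare_archetypes
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data frame with columns `feature`, `alpha`, `beta`, `test`,
#'   `statistic`, `p_value`, `tier`.
#' @export
compare_all_archetypes <- function(fm, profile, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  cs <- profile$c_effective
  nonempty <- which(profile$n_members > 0L)
  rows <- list()
  for (j in seq_along(fm$feature_names)) {
    for (ai in seq_along(nonempty)) {
      for (bi in seq_along(nonempty)) {
        if (bi <= ai) next
        a <- nonempty[ai]; b <- nonempty[bi]
        cmp <- compare_archetypes(fm, profile, a, b, j)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = fm$feature_names[j], alpha = a, beta = b,
          test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
          tier = cmp$tier, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_adjusted <- p.adjust(out$p_value, method = "holm")
    out$tier <- ifelse(out$p_adjusted < 0.001, "<<<",
                       ifelse(out$p_adjusted < 0.01, "<<",
                              ifelse(out$p_adjusted < 0.05, "<", "")))
  }
  rownames(out) <- NULL
  out
}

#' Archetypes whose typical range contains a value
#'
#' Returns every archetype whose typical range (weighted mean +/- weighted
#' SD) contains the given raw feature value -- the machinery behind
#' color-coding table entries by archetype, where a value inside several
#' ranges gets a "gradient" of colors. The result may be empty.
#'
#' @param value raw feature value.
#' @param profile an [weighted_profile()] result.
#' @param feature feature name or index.
#' @return integer vector of archetype indices (possibly empty).
#' @export
feature_color_code <- function(value, profile, feature) {
  stopifnot(inherits(profile, "archetype_profile"))
  if (is.character(feature)) {
    j <- match(feature, profile$feature_names)
    if (is.na(j)) stop(sprintf("unknown feature: %s", feature))
  } else {
    j <- as.integer(feature)
    if (j < 1L || j > length(profile$feature_names))
      stop("unknown feature index")
  }
  lo <- profile$range_low[, j]; hi <- profile$range_high[, j]
  which(!is.na(lo) & value >= lo & value <= hi)
}
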