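#' Specification of a synthetic phenotype continuum
#'
#' Describes a dataset with G well-separated archetype centroids in
#' standardized feature space, archetypal cells (centroid plus isotropic
#' Gaussian noise), transition/edge cells placed at convex combinations of
#' two or three centroids with known mixing weights, and boolean molecular
#' markers drawn per archetype from Bernoulli probabilities (interpolated
#' linearly in the mixing weights for transition cells, so that an edge cell
#' can express the distinctive markers of both parent archetypes).
#'
#' The default scenario -- 4 archetypes at minimum separation 8 with unit
#' within-archetype noise, 40 archetypal cells per archetype and 10
#' half-and-half edge cells per consecutive archetype pair -- is the
#' parameter-recovery benchmark used throughout the package tests.
#'
#' @param G number of archetypes (>= 2).
#' @param F_cont,F_bool numbers of continuous and boolean features; the
#'   defaults mirror the dimensionality typical of multimodal interneuron
#'   surveys (33 continuous measurements, 10 molecular markers).
#' @param separation minimum pairwise centroid distance in standardized
#'   units (default 8).
#' @param sigma_within within-archetype isotropic noise SD (default 1).
#' @param n_archetypal archetypal cells per archetype (scalar or length G).
#' @param transition_cells list of entries `list(archetypes =, weights =,
#'   count =)` placing `count` cells at the convex combination of the given
#'   archetype centroids; `NULL` (default) places 10 cells with weights
#'   (0.5, 0.5) on every consecutive archetype pair.
#' @param marker_probs G x F_bool matrix of Bernoulli probabilities;
#'   default: each marker is distinctive of one archetype (assigned
#'   cyclically), with occurrence 0.9 there and 0.05 elsewhere.
#' @param centroids optional G x F_cont matrix of centroids to use verbatim
#'   (bypasses random placement; lets tests control geometry).
#' @param rng_seed integer seed; the whole dataset is reproducible from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(G = 4L, F_cont = 33L, F_bool = 10L,
                           separation = 8, sigma_within = 1,
                           n_archetypal = 40L, transition_cells = NULL,
                           marker_probs = NULL, centroids = NULL,
                           rng_seed = 1L) {
  stopifnot(G >= 2L, F_cont >= 1L, F_bool >= 0L, separation > 0,
            sigma_within >= 0)
  if (length(n_archetypal) == 1L) n_archetypal <- rep(n_archetypal, G)
  stopifnot(length(n_archetypal) == G, all(n_archetypal >= 0L))
  if (is.null(transition_cells)) {
    transition_cells <- if (G >= 2L)
      lapply(seq_len(G - 1L), function(g)
        list(archetypes = c(g, g + 1L), weights = c(0.5, 0.5), count = 10L))
    else list()
  }
  for (tc in transition_cells) {
    stopifnot(length(tc$archetypes) == length(tc$weights),
              all(tc$archetypes >= 1L), all(tc$archetypes <= G),
              all(tc$weights >= 0), abs(sum(tc$weights) - 1) < 1e-9,
              tc$count >= 1L)
  }
  if (is.null(marker_probs) && F_bool > 0L) {
    # each marker is distinctive of one archetype (cyclic assignment):
    # occurrence 0.9 in its archetype, 0.05 background elsewhere
    marker_probs <- matrix(0.05, G, F_bool)
    for (m in seq_len(F_bool)) marker_probs[(m - 1L) %% G + 1L, m] <- 0.9
  }
  if (F_bool > 0L)
    stopifnot(nrow(marker_probs) == G, ncol(marker_probs) == F_bool,
              all(marker_probs >= 0 & marker_probs <= 1))
  if (!is.null(centroids))
    stopifnot(nrow(centroids) == G, ncol(centroids) == F_cont)
  structure(list(G = as.integer(G), F_cont = as.integer(F_cont),
                 F_bool = as.integer(F_bool), separation = separation,
                 sigma_within = sigma_within,
                 n_archetypal = as.integer(n_archetypal),
                 transition_cells = transition_cells,
                 marker_probs = marker_probs, centroids = centroids,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic phenotype dataset
#'
#' Draws centroids by rejection sampling until all pairwise distances reach
#' the requested separation (error after 1000 rounds, advising a lower
#' separation or more dimensions), then generates archetypal and transition
#' cells and boolean markers as described in [synthetic_spec()]. Identical
#' spec and seed give a bit-identical dataset.
#'
#' The ground truth records, per cell, the full mixing-weight vector and a
#' dominant archetype. Cells whose maximal mixing weight is exactly tied
#' (e.g. 0.5/0.5 edge cells) have no well-defined dominant archetype a
#' priori; the tie is resolved by realized proximity, i.e. the tied
#' archetype whose centroid is closest to the generated cell.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: `fm` (a
#'   [feature_matrix()]), `truth` (data frame: cell_id, dominant,
#'   is_transition), `weights` (N x G mixing weights), `centroids`
#'   (G x F_cont) and the `spec` echo.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed, {
    ctr <- spec$centroids
    if (is.null(ctr)) {
      scale <- spec$separation / sqrt(2 * spec$F_cont)
      ok <- FALSE
      for (round in seq_len(1000L)) {
        ctr <- matrix(rnorm(spec$G * spec$F_cont, sd = scale),
                      spec$G, spec$F_cont)
        if (spec$G < 2L || min(dist(ctr)) >= spec$separation) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place centroids at the requested separation; ",
             "lower 'separation' or increase 'F_cont'")
    }

    W <- matrix(0, 0, spec$G)
    for (g in seq_len(spec$G)) {
      if (spec$n_archetypal[g] == 0L) next
      w <- matrix(0, spec$n_archetypal[g], spec$G); w[, g] <- 1
      W <- rbind(W, w)
    }
    is_trans <- rep(FALSE, nrow(W))
    for (tc in spec$transition_cells) {
      w <- matrix(0, tc$count, spec$G)
      w[, tc$archetypes] <- matrix(tc$weights, tc$count,
                                   length(tc$weights), byrow = TRUE)
      W <- rbind(W, w)
      is_trans <- c(is_trans, rep(TRUE, tc$count))
    }
    n <- nrow(W)
    if (n < 2L) stop("spec generates fewer than 2 cells")

    cont <- W %*% ctr +
      matrix(rnorm(n * spec$F_cont, sd = spec$sigma_within), n, spec$F_cont)
    colnames(cont) <- sprintf("ephys_%02d", seq_len(spec$F_cont))

    if (spec$F_bool > 0L) {
      p <- W %*% spec$marker_probs
      bool <- matrix(rbinom(n * spec$F_bool, 1L, as.vector(p)),
                     n, spec$F_bool)
      colnames(bool) <- sprintf("marker_%02d", seq_len(spec$F_bool))
      raw <- cbind(cont, bool)
      kinds <- c(rep("continuous", spec$F_cont), rep("boolean", spec$F_bool))
    } else {
      raw <- cont
      kinds <- rep("continuous", spec$F_cont)
    }
    cell_ids <- sprintf("cell_%04d", seq_len(n))
    rownames(raw) <- cell_ids

    # dominant archetype; exact ties resolved by realized proximity
    dominant <- integer(n)
    for (i in seq_len(n)) {
      mx <- max(W[i, ])
      tied <- which(W[i, ] == mx)
      if (length(tied) == 1L) dominant[i] <- tied
      else {
        d2 <- colSums((t(ctr[tied, , drop = FALSE]) - cont[i, ])^2)
        dominant[i] <- tied[which.min(d2)]
      }
    }

    fm <- feature_matrix(raw, kinds)
    rownames(W) <- cell_ids
    structure(list(fm = fm,
                   truth = data.frame(cell_id = cell_ids,
                                      dominant = dominant,
                                      is_transition = is_trans,
                                      stringsAsFactors = FALSE),
                   weights = W, centroids = ctr, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d cells (%d transition), %d archetypes, %d+%d features\n",
    nrow(x$weights), sum(x$truth$is_transition), x$spec$G,
    x$spec$F_cont, x$spec$F_bool))
  invisible(x)
}

#' Ground-truth recovery metrics for a fitted partition
#'
#' Matches fitted clusters to generating archetypes by the assignment
#' maximizing total membership-mass overlap with the ground-truth mixing
#' weights, then reports (i) the adjusted Rand index between
#' argmax-membership cluster labels and ground-truth dominant archetypes and
#' (ii) the Spearman correlation between fitted memberships and true mixing
#' weights over all (cell, matched archetype) pairs. When the effective
#' cluster count differs from G, metrics cover the matched clusters only and
#' the mismatch is flagged.
#'
#' @param dataset a [generate_synthetic()] result.
#' @param partition a `fuzzy_partition` fitted on `dataset$fm`.
#' @return list with `ari`, `weight_correlation`, `mapping` (fitted cluster
#'   -> archetype) and `c_mismatch`.
#' @export
recovery_metrics <- function(dataset, partition) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            inherits(partition, "fuzzy_partition"))
  M <- partition$memberships
  W <- dataset$weights
  stopifnot(nrow(M) == nrow(W))
  labels <- apply(M, 1L, which.max)
  ari <- mclust::adjustedRandIndex(labels, dataset$truth$dominant)

  mapping <- .assign_clusters(.overlap_matrix(M, W))
  matched <- which(!is.na(mapping))
  wc <- if (length(matched)) {
    cor(as.vector(M[, matched, drop = FALSE]),
        as.vector(W[, mapping[matched], drop = FALSE]),
        method = "spearman")
  } else NA_real_

  mismatch <- ncol(M) != ncol(W)
  if (mismatch)
    warning(sprintf("c* = %d differs from G = %d; metrics use matched clusters",
                    ncol(M), ncol(W)))
  list(ari = ari, weight_correlation = wc, mapping = mapping,
       c_mismatch = mismatch)
}

#' Benchmark scenario: two archetypes separated by one planted feature
#'
#' Two archetypes whose centroids differ only along the first feature
#' (separation `separation`), plus `f_noise` pure-noise features -- the
#' canonical test bed for reduced classification on a single
#' discriminative column. Cells are archetypal only.
#'
#' @param n_per cells per archetype (default 75).
#' @param f_noise number of noise features (default 9).
#' @param separation distance between the two centroids along the planted
#'   feature (default 8).
#' @param rng_seed integer seed.
#' @return a [synthetic_spec()]; the planted feature is `ephys_01`.
#' @export
planted_feature_spec <- function(n_per = 75L, f_noise = 9L, separation = 8,
                                 rng_seed = 1L) {
  ctr <- matrix(0, 2L, f_noise + 1L)
  ctr[1L, 1L] <- separation / 2
  ctr[2L, 1L] <- -separation / 2
  synthetic_spec(G = 2L, F_cont = f_noise + 1L, F_bool = 0L,
                 centroids = ctr, separation = separation,
                 n_archetypal = n_per, transition_cells = list(),
                 rng_seed = rng_seed)
}

#' Benchmark centroids with hierarchical separations
#'
#' Three archetype centroids with one close pair (distance `d_close`) and a
#' distant third (distance `d_far` from the first), the contrasts spread
#' over random orthogonal directions. Axis-aligned contrasts would be
#' flattened by per-feature standardization (each feature is scaled to unit
#' variance, equalizing per-axis separations); spreading them across many
#' features preserves the intended hierarchy in standardized space.
#'
#' @param f_cont number of continuous features (>= 2).
#' @param d_close,d_far pairwise centroid distances (defaults 2 and 12).
#' @param rng_seed integer seed for the random directions.
#' @return a 3 x `f_cont` centroid matrix (archetypes 1 and 2 are the close
#'   pair).
#' @export
hierarchy_centroids <- function(f_cont = 33L, d_close = 2, d_far = 12,
                                rng_seed = 1L) {
  stopifnot(f_cont >= 2L, d_close > 0, d_far > d_close)
  withr::with_seed(as.integer(rng_seed), {
    u <- rnorm(f_cont); u <- u / sqrt(sum(u^2))
    v <- rnorm(f_cont); v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
    rbind(0 * u, d_close * u, d_far * v)
  })
}
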