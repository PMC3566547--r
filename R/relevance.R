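#' Scramble feature columns
#'
#' Independently permutes the entries of the selected columns across cells,
#' leaving every other column untouched. Per-column value multisets (hence
#' means and standard deviations) are preserved by construction; what the
#' scrambling destroys is the correlation of the scrambled features with the
#' rest of the table. Raw and standardized values are permuted identically,
#' which equals re-standardizing the scrambled raw column.
#'
#' @param fm a [feature_matrix()].
#' @param subset feature names or indices to scramble (non-empty).
#' @param rng_seed integer seed; each column gets an independent permutation
#'   from this stream.
#' @return a new `feature_matrix` with the selected columns scrambled.
#' @export
scramble_features <- function(fm, subset, rng_seed) {
  stopifnot(inherits(fm, "feature_matrix"), length(subset) >= 1L)
  js <- .feature_index(fm, subset)
  n <- nrow(fm$raw)
  out <- fm
  withr::with_seed(as.integer(rng_seed), {
    for (j in js) {
      perm <- sample.int(n)
      out$raw[, j] <- fm$raw[perm, j]
      out$standardized[, j] <- fm$standardized[perm, j]
    }
  })
  out
}

#' Cost increase from scrambling a feature subset
#'
#' Quantifies how much a subset of features contributes to the structure
#' captured by the reference fuzzy partition: each of `R` replicates
#' scrambles the subset, refits with the identical configuration and seeds
#' (so that cost differences reflect the scrambling, not initialization
#' noise), and records the relative cost increase
#' `100 * (J_scrambled - J_ref) / J_ref` in percent. The converged
#' pre-coalescence cost J is used on both sides.
#'
#' Replicates whose fit fails are logged and excluded; the effective
#' replicate count is reported.
#'
#' @param fm a [feature_matrix()].
#' @param subset feature names or indices to scramble together.
#' @param config an [fcm_config()] shared by the reference and all refits.
#' @param R number of independent randomizations (default 1000).
#' @param rng_seed integer seed for the scrambling streams; replicate r uses
#'   `rng_seed + r`.
#' @param reference optionally a precomputed reference `fuzzy_partition`
#'   fitted on `fm` with `config`.
#' @return list with `mean`, `sd` (of the percentage cost increases),
#'   `delta_j` (all replicate values), `R_effective` and `j_ref`.
#' @export
delta_cost <- function(fm, subset, config, R = 1000L, rng_seed = config$rng_seed,
                       reference = NULL) {
  stopifnot(R >= 2L)
  if (is.null(reference)) reference <- fcm_fit(fm, config)
  j_ref <- reference$cost
  # lean replicate loop: permute the standardized columns directly and run
  # the compiled core from the same initial cells as the reference fit
  # (J is the pre-coalescence cost, so no post-processing is needed)
  X <- fm$standardized
  js <- .feature_index(fm, subset)
  inits <- .init_indices(config, nrow(X))
  deltas <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    deltas[r] <- tryCatch({
      Xs <- X
      withr::with_seed(as.integer(rng_seed) + r, {
        for (j in js) Xs[, j] <- X[sample.int(nrow(X)), j]
      })
      j_s <- min(vapply(inits, function(idx)
        .fcm_core(Xs, Xs[idx, , drop = FALSE], config$mu, config$tol,
                  config$max_iter)$cost, numeric(1)))
      100 * (j_s - j_ref) / j_ref
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      NA_real_
    })
  }
  ok <- !is.na(deltas)
  list(mean = mean(deltas[ok]), sd = sd(deltas[ok]), delta_j = deltas,
       R_effective = sum(ok), j_ref = j_ref)
}

#' Rank features by scrambling cost increase
#'
#' Applies [delta_cost()] to every feature singly and ranks features in
#' descending order of mean cost increase; ties are broken by feature order
#' in the input table. Features at the top of the ranking are the most
#' decisive for the extracted partition.
#'
#' @inheritParams delta_cost
#' @return an object of class `relevance_report`: data frame `ranking` with
#'   columns `rank`, `feature`, `delta_j_mean`, `delta_j_sd`, `R_effective`,
#'   plus `R` and `rng_seed` echoes.
#' @export
rank_features <- function(fm, config, R = 1000L, rng_seed = config$rng_seed) {
  reference <- fcm_fit(fm, config)
  f <- length(fm$feature_names)
  # one independent scramble-seed base per feature, derived reproducibly
  bases <- withr::with_seed(as.integer(rng_seed),
                            sample.int(2^30, f)) # headroom: base + R < 2^31
  res <- lapply(seq_len(f), function(j)
    delta_cost(fm, j, config, R = R, rng_seed = bases[j],
               reference = reference))
  tab <- data.frame(
    feature = fm$feature_names,
    delta_j_mean = vapply(res, `[[`, numeric(1), "mean"),
    delta_j_sd = vapply(res, `[[`, numeric(1), "sd"),
    R_effective = vapply(res, `[[`, numeric(1), "R_effective"))
  ord <- order(-tab$delta_j_mean, seq_len(f))
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(f), tab)
  rownames(tab) <- NULL
  structure(list(ranking = tab, R = R, rng_seed = rng_seed,
                 j_ref = reference$cost),
            class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, ...) {
  cat(sprintf("relevance_report: %d features, R = %d\n",
              nrow(x$ranking), x$R))
  print(head(x$ranking, 10L))
  invisible(x)
}

#' Reduced classification from the top-K ranked features
#'
#' Refits the partition using only the K top-ranked features (re-standardized,
#' with the same configuration and seeding as the reference fit on all
#' features), maps each reduced cluster to the reference archetype with the
#' largest mutual membership-mass overlap (solving the assignment problem
#' that maximizes total overlap), and reports the percentage of cells whose
#' reduced main type maps to their reference main type -- per archetype and
#' overall.
#'
#' @param fm a [feature_matrix()].
#' @param ranking a `relevance_report`, or a character vector of feature
#'   names already in descending relevance order.
#' @param K number of top features to keep, 1 <= K <= F.
#' @param config an [fcm_config()] shared with the reference fit.
#' @return list with `K`, `features_used`, `mapping` (reduced cluster ->
#'   reference archetype, NA where unmatched), `per_archetype` (data frame:
#'   archetype, n_cells, matching_fraction %), and `overall_matching` (%).
#' @export
reduced_classification <- function(fm, ranking, K, config) {
  feats <- if (inherits(ranking, "relevance_report"))
    ranking$ranking$feature else as.character(ranking)
  f <- length(fm$feature_names)
  if (K < 1L || K > f) stop("K must lie between 1 and the number of features")
  top <- feats[seq_len(K)]

  reference <- fcm_fit(fm, config)
  reduced <- fcm_fit(subset_features(fm, top), config)

  main_ref <- apply(reference$memberships, 1L, which.max)
  main_red <- apply(reduced$memberships, 1L, which.max)

  O <- .overlap_matrix(reduced$memberships, reference$memberships)
  mapping <- .assign_clusters(O) # index: reduced cluster, value: ref archetype

  mapped <- mapping[main_red]
  per <- lapply(seq_len(ncol(reference$memberships)), function(a) {
    I <- which(main_ref == a)
    data.frame(archetype = a, n_cells = length(I),
               matching_fraction = if (length(I))
                 100 * mean(mapped[I] == a, na.rm = FALSE) else NA_real_)
  })
  per <- do.call(rbind, per)
  per$matching_fraction[is.na(per$matching_fraction)] <-
    ifelse(per$n_cells[is.na(per$matching_fraction)] > 0, 0, NA)
  overall <- 100 * mean(mapped == main_ref, na.rm = FALSE)
  if (is.na(overall)) overall <- 100 * mean(!is.na(mapped) & mapped == main_ref)

  list(K = K, features_used = top, mapping = mapping,
       per_archetype = per, overall_matching = overall,
       reference = reference, reduced = reduced)
}

# Maximize total overlap assignment between row clusters and column
# clusters. Exhaustive over permutations when the smaller side has <= 8
# clusters (exact), greedy otherwise. Returns, per row cluster, the matched
# column index (NA if unmatched).
.assign_clusters <- function(O) {
  nr <- nrow(O); nc <- ncol(O)
  mapping <- rep(NA_integer_, nr)
  k <- min(nr, nc); n <- max(nr, nc)
  n_perms <- prod(seq.int(n, n - k + 1L))
  if (n_perms <= 2e5) {
    if (nr <= nc) {
      perms <- .permutations(nc, nr)
      scores <- vapply(seq_len(nrow(perms)), function(k)
        sum(O[cbind(seq_len(nr), perms[k, ])]), numeric(1))
      mapping <- perms[which.max(scores), ]
    } else {
      perms <- .permutations(nr, nc)
      scores <- vapply(seq_len(nrow(perms)), function(k)
        sum(O[cbind(perms[k, ], seq_len(nc))]), numeric(1))
      best <- perms[which.max(scores), ]
      mapping[best] <- seq_len(nc)
    }
  } else {
    W <- O
    repeat {
      if (all(is.na(W)) || max(W, na.rm = TRUE) < 0) break
      ij <- which(W == max(W, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      mapping[ij[1L]] <- ij[2L]
      W[ij[1L], ] <- NA; W[, ij[2L]] <- NA
      if (all(is.na(W))) break
    }
  }
  mapping
}

# all ordered selections of k elements out of n (n!/(n-k)! rows)
.permutations <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- matrix(seq_len(n), ncol = 1L)
  for (col in seq_len(k - 1L)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      row <- out[r, ]
      rest <- setdiff(seq_len(n), row)
      cbind(matrix(row, nrow = length(rest), ncol = length(row),
                   byrow = TRUE), rest)
    }))
  }
  unname(out)
}
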