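#' Fuzzy c-means configuration
#'
#' Bundles the tunable parameters of a fuzzy c-means fit. The fuzziness
#' exponent `mu` (> 1) controls partition softness: close to 1 the algorithm
#' behaves like crisp k-means, large values merge all clusters. `c_max` is
#' the maximally allowed number of clusters; coalescence of converged
#' centroids closer than `epsilon` (standardized units) reduces it to the
#' effective count c*. `seed_points` are cell indices used as fixed initial
#' centroids (a seeding pre-initialization); the remaining
#' `c_max - length(seed_points)` initial centroids are distinct cells drawn
#' without replacement using `rng_seed`.
#'
#' @param mu fuzziness parameter, real > 1.
#' @param rng_seed integer seed governing the random part of the
#'   initialization (mandatory, echoed in all outputs).
#' @param c_max maximum cluster count (default 20).
#' @param tol convergence threshold on the maximum absolute centroid
#'   displacement between iterations (default 1e-6, standardized units).
#' @param max_iter maximum number of alternating iterations (default 300).
#' @param epsilon coalescence threshold on pairwise centroid distance
#'   (default 0.001, standardized units).
#' @param seed_points integer vector of cell indices used as fixed initial
#'   centroids (possibly empty).
#' @param n_restarts number of restarts (default 1); restarts share
#'   `seed_points` and differ in the random complement, the run with the
#'   lowest final cost is kept.
#' @return an object of class `fcm_config`.
#' @export
fcm_config <- function(mu, rng_seed, c_max = 20L, tol = 1e-6,
                       max_iter = 300L, epsilon = 0.001,
                       seed_points = integer(0), n_restarts = 1L) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 1,
            is.numeric(rng_seed), length(rng_seed) == 1L,
            c_max >= 2L, tol > 0, max_iter >= 1L, epsilon > 0,
            n_restarts >= 1L)
  seed_points <- as.integer(seed_points)
  if (anyDuplicated(seed_points)) stop("seed_points must be distinct")
  if (length(seed_points) > c_max)
    stop("more seed_points than c_max")
  structure(list(mu = mu, rng_seed = as.integer(rng_seed),
                 c_max = as.integer(c_max), tol = tol,
                 max_iter = as.integer(max_iter), epsilon = epsilon,
                 seed_points = seed_points,
                 n_restarts = as.integer(n_restarts)),
            class = "fcm_config")
}

#' Membership vectors for given centroids
#'
#' For cell i and cluster a, `1/m_ia = sum_l (d_ia / d_il)^(2/(mu-1))` with
#' Euclidean distances in standardized space, so that each row sums to 1. A
#' cell coinciding with one or more centroids (distance < 1e-12) splits its
#' membership equally among the coincident centroids.
#'
#' @param data a [feature_matrix()] or a numeric matrix in standardized
#'   space.
#' @param centroids numeric matrix, one centroid per row.
#' @param mu fuzziness parameter > 1.
#' @return N x c membership matrix with unit row sums.
#' @examples
#' fcm_memberships(matrix(0), matrix(c(1, 2)), mu = 2) # distances 1 and 2
#' @export
fcm_memberships <- function(data, centroids, mu) {
  X <- .std_data(data)
  if (!is.matrix(centroids)) centroids <- matrix(centroids, ncol = ncol(X))
  stopifnot(ncol(centroids) == ncol(X), nrow(centroids) >= 1L, mu > 1)
  M <- .fcm_memberships_cpp(X, centroids, mu)
  dimnames(M) <- list(rownames(X), rownames(centroids))
  M
}

#' Centroid update from memberships
#'
#' `u_al = sum_i m_ia^mu f_il / sum_i m_ia^mu`: each centroid is the mean of
#' all cells weighted by the mu-th power of their memberships.
#'
#' @inheritParams fcm_memberships
#' @param memberships N x c membership matrix with unit row sums.
#' @return c x F centroid matrix.
#' @export
fcm_centroids <- function(data, memberships, mu) {
  X <- .std_data(data)
  M <- as.matrix(memberships)
  stopifnot(nrow(M) == nrow(X), mu > 1)
  if (max(abs(rowSums(M) - 1)) > 1e-6)
    stop("membership rows must sum to 1")
  W <- M^mu
  cs <- colSums(W)
  if (any(cs <= 0)) stop("empty cluster: a membership column has zero total weight")
  U <- crossprod(W, X) / cs
  rownames(U) <- colnames(M)
  U
}

#' Fuzzy clustering cost
#'
#' `J = sum_i sum_l m_il^mu * d_il^2`, the membership-weighted sum of squared
#' cell-to-centroid distances that the alternating updates minimize.
#'
#' @inheritParams fcm_centroids
#' @param centroids c x F centroid matrix.
#' @return non-negative scalar cost.
#' @export
fcm_cost <- function(data, memberships, centroids, mu) {
  X <- .std_data(data)
  M <- as.matrix(memberships)
  U <- as.matrix(centroids)
  stopifnot(nrow(M) == nrow(X), ncol(M) == nrow(U), ncol(U) == ncol(X))
  D2 <- outer(rowSums(X^2), rep(1, nrow(U))) +
    outer(rep(1, nrow(X)), rowSums(U^2)) - 2 * X %*% t(U)
  D2[D2 < 0] <- 0
  sum(M^mu * D2)
}

#' Fit a fuzzy c-means partition
#'
#' Alternates membership and centroid updates from a seeded initialization
#' until the maximum absolute centroid displacement falls below `tol` (or
#' `max_iter` is reached, in which case the partition is returned with
#' `converged = FALSE` and a warning), then merges converged centroids closer
#' than `epsilon` (see [coalesce()]). The recorded `cost` is the converged
#' pre-coalescence cost J; `cost_trace` holds J at every iteration and is
#' non-increasing.
#'
#' @param data a [feature_matrix()] (or a numeric matrix already in
#'   standardized space).
#' @param config an [fcm_config()].
#' @return an object of class `fuzzy_partition` with elements `centroids`
#'   (c* x F), `memberships` (N x c*, unit row sums), `mu`, `cost`,
#'   `cost_trace`, `n_iterations`, `converged`, `coalescence_log` (list of
#'   merged pre-merge cluster index groups), `c_effective`, `init_indices`
#'   and a `config` echo.
#' @examples
#' fm <- feature_matrix(matrix(c(rnorm(20), rnorm(20, 10)), ncol = 2),
#'                      kinds = "continuous")
#' p <- fcm_fit(fm, fcm_config(mu = 1.349, rng_seed = 1, c_max = 4))
#' p$c_effective
#' @export
fcm_fit <- function(data, config) {
  stopifnot(inherits(config, "fcm_config"))
  X <- .std_data(data)
  n <- nrow(X)
  if (config$c_max > n) stop("c_max cannot exceed the number of cells")
  if (length(config$seed_points) &&
      (min(config$seed_points) < 1L || max(config$seed_points) > n))
    stop("seed_points must be valid cell indices")

  inits <- .init_indices(config, n)
  runs <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    init_idx <- inits[[r]]
    fit <- .fcm_core(X, X[init_idx, , drop = FALSE], config$mu,
                     config$tol, config$max_iter)
    fit$init_indices <- init_idx
    runs[[r]] <- fit
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  if (!best$converged)
    warning(sprintf("fcm did not converge in %d iterations", config$max_iter))

  rownames(best$memberships) <- rownames(X)
  part <- structure(
    list(centroids = best$centroids, memberships = best$memberships,
         mu = config$mu, cost = best$cost, cost_trace = best$cost_trace,
         n_iterations = best$n_iterations, converged = best$converged,
         coalescence_log = list(), c_effective = nrow(best$centroids),
         init_indices = best$init_indices, config = config),
    class = "fuzzy_partition")
  coalesce(part, config$epsilon)
}

# initial centroid cell indices per restart: the fixed seed_points plus a
# random complement drawn without replacement from rng_seed (+ r - 1)
.init_indices <- function(config, n) {
  free <- setdiff(seq_len(n), config$seed_points)
  k_extra <- config$c_max - length(config$seed_points)
  lapply(seq_len(config$n_restarts), function(r) {
    extra <- if (k_extra > 0L)
      withr::with_seed(config$rng_seed + r - 1L, sample(free, k_extra))
    else integer(0)
    c(config$seed_points, extra)
  })
}

#' Merge coalesced clusters
#'
#' Clusters whose converged centroids lie within `epsilon` of each other are
#' grouped by single-linkage transitive closure; each group's membership
#' columns are summed and its representative centroid is the arithmetic mean
#' of the group's centroids (group members differ by less than `epsilon`, so
#' any representative is equivalent to that tolerance). No further
#' optimization iterations are run after merging.
#'
#' @param partition a `fuzzy_partition`.
#' @param epsilon coalescence distance threshold.
#' @return the partition with `c_effective` clusters, merge events appended
#'   to `coalescence_log`.
#' @export
coalesce <- function(partition, epsilon) {
  stopifnot(inherits(partition, "fuzzy_partition"), epsilon > 0)
  U <- partition$centroids
  c0 <- nrow(U)
  if (c0 == 1L) {
    partition$c_effective <- 1L
    return(partition)
  }
  D <- as.matrix(dist(U))
  # transitive closure of the "closer than epsilon" relation (union-find)
  comp <- seq_len(c0)
  for (a in seq_len(c0 - 1L)) for (b in seq.int(a + 1L, c0)) {
    if (D[a, b] < epsilon) {
      ca <- comp[a]; cb <- comp[b]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  groups <- split(seq_len(c0), comp)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  if (length(groups) == c0) return(partition) # nothing to merge

  newU <- do.call(rbind, lapply(groups, function(g)
    colMeans(U[g, , drop = FALSE])))
  newM <- do.call(cbind, lapply(groups, function(g)
    rowSums(partition$memberships[, g, drop = FALSE])))
  rownames(newU) <- NULL
  rownames(newM) <- rownames(partition$memberships)
  colnames(newM) <- NULL
  partition$centroids <- newU
  partition$memberships <- newM
  partition$c_effective <- length(groups)
  merged <- Filter(function(g) length(g) > 1L, groups)
  partition$coalescence_log <- c(partition$coalescence_log,
                                 unname(lapply(merged, as.integer)))
  partition
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf(
    "fuzzy_partition: %d cells, c* = %d (mu = %g, J = %.6g, %d iterations%s)\n",
    nrow(x$memberships), x$c_effective, x$mu, x$cost, x$n_iterations,
    if (x$converged) "" else ", NOT converged"))
  if (length(x$coalescence_log))
    cat(sprintf("  coalescence: %d merge group(s)\n", length(x$coalescence_log)))
  invisible(x)
}
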