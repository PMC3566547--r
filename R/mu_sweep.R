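#' Sweep the fuzziness parameter
#'
#' Fits one coalesced partition per grid value of the fuzziness parameter,
#' reusing the same seed cells and RNG seed at every mu so that partitions
#' are comparable, and tracks cluster identity across adjacent grid points
#' ("lineages") by greedily matching the cluster pairs sharing the largest
#' summed membership mass. The resulting curve of the effective cluster
#' count c*(mu) charts the emergence hierarchy of archetypes: c* decreases
#' as mu grows and clusters coalesce.
#'
#' A fit failure at a single grid point is logged as a warning and that
#' point marked invalid without aborting the sweep.
#'
#' @param data a [feature_matrix()].
#' @param config an [fcm_config()]; its `mu` is ignored in favor of the grid.
#' @param mu_grid strictly increasing vector of fuzziness values in (1, 2]
#'   (upper bound configurable via `mu_max`). Default: steps of 0.01 over
#'   [1.05, 1.95].
#' @param mu_max upper bound allowed for the grid (default 2).
#' @return an object of class `mu_sweep_result`: `mu_grid`, `partitions`
#'   (list, `NULL` where invalid), `c_effective` (c* per mu, `NA` where
#'   invalid), `valid`, and `lineages` (per grid point, an integer lineage
#'   id per cluster).
#' @export
mu_sweep <- function(data, config, mu_grid = seq(1.05, 1.95, by = 0.01),
                     mu_max = 2) {
  stopifnot(inherits(config, "fcm_config"))
  if (is.unsorted(mu_grid, strictly = TRUE))
    stop("mu_grid must be strictly increasing")
  if (any(mu_grid <= 1) || any(mu_grid > mu_max))
    stop(sprintf("mu_grid values must lie in (1, %g]", mu_max))

  k <- length(mu_grid)
  partitions <- vector("list", k)
  c_eff <- rep(NA_integer_, k)
  valid <- logical(k)
  for (t in seq_len(k)) {
    cfg <- config
    cfg$mu <- mu_grid[t]
    p <- tryCatch(fcm_fit(data, cfg), error = function(e) {
      warning(sprintf("fit failed at mu = %g: %s", mu_grid[t],
                      conditionMessage(e)))
      NULL
    })
    partitions[[t]] <- p
    if (!is.null(p)) { c_eff[t] <- p$c_effective; valid[t] <- TRUE }
  }

  # lineage ids: new ids at the first valid point, then greedy matching of
  # adjacent partitions on shared membership mass sum_i min(m_ia, m_ib)
  lineages <- vector("list", k)
  next_id <- 1L
  prev <- NULL
  for (t in seq_len(k)) {
    if (!valid[t]) { lineages[[t]] <- integer(0); next }
    cur <- partitions[[t]]$memberships
    ids <- rep(NA_integer_, ncol(cur))
    if (!is.null(prev)) {
      O <- .overlap_matrix(prev$m, cur)
      repeat {
        if (all(is.na(O)) || max(O, na.rm = TRUE) <= 0) break
        ij <- which(O == max(O, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        ids[ij[2L]] <- prev$ids[ij[1L]]
        O[ij[1L], ] <- NA; O[, ij[2L]] <- NA
        if (all(is.na(O))) break
      }
    }
    for (j in which(is.na(ids))) { ids[j] <- next_id; next_id <- next_id + 1L }
    lineages[[t]] <- ids
    prev <- list(m = cur, ids = ids)
  }

  structure(list(mu_grid = mu_grid, partitions = partitions,
                 c_effective = c_eff, valid = valid, lineages = lineages,
                 config = config),
            class = "mu_sweep_result")
}

# shared membership mass between cluster columns of two membership matrices
.overlap_matrix <- function(M1, M2) {
  O <- matrix(0, ncol(M1), ncol(M2))
  for (a in seq_len(ncol(M1))) for (b in seq_len(ncol(M2)))
    O[a, b] <- sum(pmin(M1[, a], M2[, b]))
  O
}

#' Robust ranges of the effective cluster count
#'
#' Finds the maximal contiguous runs of grid points with constant c* and
#' flags runs narrower than `min_width` as non-robust (partitions valid only
#' in a sliver of fuzziness values are not trustworthy).
#'
#' @param sweep a [mu_sweep()] result, or a plain integer c* curve paired
#'   with `mu_grid`.
#' @param min_width minimal mu-width for a range to count as robust
#'   (default 0.05).
#' @param mu_grid grid values, required when `sweep` is a plain vector.
#' @return data frame with columns `c_star`, `mu_low`, `mu_high`, `width`,
#'   `robust`, one row per maximal run (invalid grid points break runs).
#' @export
robust_ranges <- function(sweep, min_width = 0.05, mu_grid = NULL) {
  if (inherits(sweep, "mu_sweep_result")) {
    curve <- sweep$c_effective
    mu_grid <- sweep$mu_grid
  } else {
    curve <- as.integer(sweep)
    if (is.null(mu_grid)) stop("mu_grid required for a plain c* curve")
  }
  stopifnot(length(curve) == length(mu_grid))
  r <- rle(ifelse(is.na(curve), -1L, curve))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != -1L
  out <- data.frame(
    c_star = r$values[keep],
    mu_low = mu_grid[starts[keep]],
    mu_high = mu_grid[ends[keep]])
  out$width <- out$mu_high - out$mu_low
  out$robust <- out$width >= min_width
  out
}

#' Fuzziness level at which a cluster lineage disappears
#'
#' Returns the largest grid mu at which the given lineage still exists as a
#' distinct (non-coalesced) cluster; at any larger mu it has merged into
#' another lineage. Formalizes statements such as "this archetype detached
#' first at mu = x".
#'
#' @param sweep a [mu_sweep()] result.
#' @param lineage integer lineage id (as assigned in `sweep$lineages`).
#' @return a single mu value.
#' @export
emergence_mu <- function(sweep, lineage) {
  stopifnot(inherits(sweep, "mu_sweep_result"))
  present <- vapply(sweep$lineages, function(ids) lineage %in% ids, logical(1))
  if (!any(present)) stop(sprintf("unknown lineage id: %s", lineage))
  max(sweep$mu_grid[present])
}

#' @export
print.mu_sweep_result <- function(x, ...) {
  cat(sprintf("mu_sweep_result: %d grid points in [%g, %g], c* from %s to %s\n",
              length(x$mu_grid), min(x$mu_grid), max(x$mu_grid),
              x$c_effective[1L], x$c_effective[length(x$c_effective)]))
  invisible(x)
}
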