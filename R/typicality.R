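#' Typicality coefficient of a single cell
#'
#' The typicality coefficient is the difference between a cell's largest and
#' second-largest membership components, `d = m_(1st) - m_(2nd)`, bounded in
#' [0, 1]. A value near 1 marks a cell fully committed to a single archetype;
#' near 0, a cell sharing its identity between its main and secondary types.
#' Ties are broken deterministically toward the lowest cluster index.
#'
#' @param membership_row numeric vector summing to 1 with at least 2
#'   components (with a single archetype typicality is undefined).
#' @return list with `main_type`, `secondary_type` (cluster indices) and `d`.
#' @examples
#' typicality(c(0.00, 0.97, 0.00, 0.00, 0.01, 0.01)) # d = 0.96
#' @export
typicality <- function(membership_row) {
  m <- as.numeric(membership_row)
  if (length(m) < 2L)
    stop("typicality is undefined with a single archetype (c* = 1)")
  # printed membership tables are rounded to two decimals; accept those
  if (abs(sum(m) - 1) > 0.02) stop("membership row must sum to 1")
  ord <- order(-m, seq_along(m)) # ties -> lowest index first
  list(main_type = ord[1L], secondary_type = ord[2L],
       d = m[ord[1L]] - m[ord[2L]])
}

#' Typicality spectrum of a sample
#'
#' Computes per-cell typicality coefficients and partitions the sample into
#' archetypal, atypical and intermediate cells using thresholds derived from
#' the sample itself: with `d_bar` the mean typicality and `Delta` the
#' halved mean absolute deviation `0.5 * mean(|d_i - d_bar|)`, a cell is
#' archetypal if `d > d_bar + Delta` and atypical if `d < d_bar - Delta`.
#' Cells between the strict thresholds are labeled intermediate. Edge cells
#' -- atypical cells lying essentially on the boundary between their main
#' and secondary archetypes -- carry an additional flag `d <= Delta`,
#' orthogonal to the 3-way label.
#'
#' @param x a `fuzzy_partition` or an N x c membership matrix (c >= 2).
#' @return an object of class `typicality_spectrum`: data frame `cells`
#'   (cell_id, main_type, secondary_type, d, label, edge_flag) plus sample
#'   statistics `d_bar`, `delta`, `d_archetypal`, `d_atypical`.
#' @export
typicality_spectrum <- function(x) {
  M <- if (inherits(x, "fuzzy_partition")) x$memberships else as.matrix(x)
  if (ncol(M) < 2L)
    stop("typicality is undefined with a single archetype (c* = 1)")
  if (nrow(M) < 2L) stop("at least 2 cells are required")
  per <- lapply(seq_len(nrow(M)), function(i) typicality(M[i, ]))
  d <- vapply(per, `[[`, numeric(1), "d")
  d_bar <- mean(d)
  delta <- 0.5 * mean(abs(d - d_bar))
  lab <- ifelse(d > d_bar + delta, "archetypal",
                ifelse(d < d_bar - delta, "atypical", "intermediate"))
  cells <- data.frame(
    cell_id = if (!is.null(rownames(M))) rownames(M) else
      paste0("cell_", seq_len(nrow(M))),
    main_type = vapply(per, `[[`, integer(1) + 0L,
                       "main_type"),
    secondary_type = vapply(per, `[[`, integer(1) + 0L, "secondary_type"),
    d = d, label = lab, edge_flag = d <= delta,
    stringsAsFactors = FALSE)
  structure(list(cells = cells, d_bar = d_bar, delta = delta,
                 d_archetypal = d_bar + delta, d_atypical = d_bar - delta,
                 c_effective = ncol(M)),
            class = "typicality_spectrum")
}

#' @export
print.typicality_spectrum <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("typicality_spectrum: %d cells, d_bar = %.3f, Delta = %.3f\n",
              n, x$d_bar, x$delta))
  cat(sprintf("  archetypal %d (%.0f%%), atypical %d (%.0f%%), intermediate %d; edge cells %d\n",
              sum(x$cells$label == "archetypal"),
              100 * mean(x$cells$label == "archetypal"),
              sum(x$cells$label == "atypical"),
              100 * mean(x$cells$label == "atypical"),
              sum(x$cells$label == "intermediate"),
              sum(x$cells$edge_flag)))
  invisible(x)
}

#' Edge-cell counts per archetype pair
#'
#' Tabulates, for every unordered (main, secondary) archetype pair, how many
#' edge-flagged cells sit on the boundary between the two.
#'
#' @param spectrum a [typicality_spectrum()].
#' @return data frame with columns `type_a`, `type_b`, `n_edge`.
#' @export
edge_pair_counts <- function(spectrum) {
  stopifnot(inherits(spectrum, "typicality_spectrum"))
  e <- spectrum$cells[spectrum$cells$edge_flag, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(type_a = integer(0), type_b = integer(0),
                      n_edge = integer(0)))
  a <- pmin(e$main_type, e$secondary_type)
  b <- pmax(e$main_type, e$secondary_type)
  agg <- table(paste(a, b, sep = "-"))
  parts <- strsplit(names(agg), "-", fixed = TRUE)
  data.frame(type_a = as.integer(vapply(parts, `[`, "", 1L)),
             type_b = as.integer(vapply(parts, `[`, "", 2L)),
             n_edge = as.integer(agg))
}

#' Two-archetype membership projection
#'
#' Projects every cell onto the plane spanned by its memberships to two
#' chosen archetypes, flagging cells inside the diagonal edge band
#' `|m_ia - m_ib| <= Delta` (the halved mean absolute deviation of the
#' typicality distribution). This is the coordinate export behind pairwise
#' archetype-segregation plots; no rendering is performed.
#'
#' @param x a `fuzzy_partition` or membership matrix.
#' @param cluster_a,cluster_b distinct cluster indices.
#' @return data frame with columns `cell_id`, `m_a`, `m_b`, `edge_band`,
#'   with the band half-width `Delta` attached as attribute `"delta"`.
#' @export
pair_projection <- function(x, cluster_a, cluster_b) {
  M <- if (inherits(x, "fuzzy_partition")) x$memberships else as.matrix(x)
  if (cluster_a == cluster_b) stop("cluster_a and cluster_b must differ")
  stopifnot(cluster_a >= 1L, cluster_b >= 1L,
            cluster_a <= ncol(M), cluster_b <= ncol(M))
  spec <- typicality_spectrum(M)
  out <- data.frame(
    cell_id = spec$cells$cell_id,
    m_a = M[, cluster_a], m_b = M[, cluster_b])
  out$edge_band <- abs(out$m_a - out$m_b) <= spec$delta
  attr(out, "delta") <- spec$delta
  rownames(out) <- NULL
  out
}
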