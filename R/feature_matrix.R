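#' Build a standardized feature matrix
#'
#' Assembles a cells-by-features table into the container used by all
#' downstream analyses. Every column is centered and reduced (z-scored using
#' the population standard deviation, i.e. dividing by N); boolean marker
#' columns are standardized for clustering exactly like continuous features,
#' while their raw 0/1 values are retained for occurrence percentages and
#' Fisher tests.
#'
#' A constant raw column cannot be scaled and is carried as all zeros with a
#' warning; it then contributes nothing to any distance, which matches its
#' information content. Missing values are a hard error naming the offending
#' cell and feature.
#'
#' @param raw numeric matrix or data frame, cells in rows, features in
#'   columns. Row names (or `cell_ids`) identify cells.
#' @param kinds character vector, one of `"continuous"` or `"boolean"` per
#'   feature. Boolean columns must contain only 0/1.
#' @param cell_ids optional character vector of cell identifiers; defaults to
#'   row names or `cell_1 ... cell_N`.
#' @return An object of class `feature_matrix` with elements `cell_ids`,
#'   `feature_names`, `kinds`, `raw` and `standardized` (both N x F
#'   matrices).
#' @examples
#' fm <- feature_matrix(cbind(x = c(1, 2, 3), m = c(0, 1, 1)),
#'                      kinds = c("continuous", "boolean"))
#' colMeans(fm$standardized)
#' @export
feature_matrix <- function(raw, kinds, cell_ids = NULL) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix or data frame")
  n <- nrow(raw); f <- ncol(raw)
  if (n < 2L) stop("at least 2 cells are required")
  if (f < 1L) stop("at least 1 feature is required")
  if (is.null(cell_ids)) cell_ids <- rownames(raw)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  feature_names <- colnames(raw)
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(f))
  kinds <- match.arg(kinds, c("continuous", "boolean"), several.ok = TRUE)
  if (length(kinds) == 1L) kinds <- rep(kinds, f)
  if (length(kinds) != f)
    stop("'kinds' must have one entry per feature")

  if (anyNA(raw)) {
    idx <- which(is.na(raw), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value for cell '%s', feature '%s'",
                 cell_ids[idx[1L]], feature_names[idx[2L]]))
  }
  for (j in which(kinds == "boolean")) {
    if (!all(raw[, j] %in% c(0, 1)))
      stop(sprintf("boolean feature '%s' contains values other than 0/1",
                   feature_names[j]))
  }

  std <- matrix(0, n, f, dimnames = list(cell_ids, feature_names))
  for (j in seq_len(f)) {
    v <- raw[, j]
    s <- sqrt(mean((v - mean(v))^2)) # population SD
    if (s == 0) {
      warning(sprintf("feature '%s' is constant; standardized to all zeros",
                      feature_names[j]))
      std[, j] <- 0
    } else {
      std[, j] <- (v - mean(v)) / s
    }
  }
  dimnames(raw) <- dimnames(std)
  structure(
    list(cell_ids = cell_ids, feature_names = feature_names, kinds = kinds,
         raw = raw, standardized = std),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d cells x %d features (%d continuous, %d boolean)\n",
              nrow(x$raw), ncol(x$raw),
              sum(x$kinds == "continuous"), sum(x$kinds == "boolean")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$raw)

# internal: accept a feature_matrix or a plain numeric matrix already in
# standardized space
.std_data <- function(x) {
  if (inherits(x, "feature_matrix")) return(x$standardized)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a feature_matrix or a numeric matrix")
}

#' Restrict a feature matrix to a subset of features
#'
#' Columns are re-standardized, which for a column subset is identical to
#' subsetting the standardized table (standardization is per column).
#'
#' @param fm a [feature_matrix()].
#' @param features character or integer vector of features to keep.
#' @return a `feature_matrix` with the selected columns.
#' @export
subset_features <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  j <- .feature_index(fm, features)
  structure(
    list(cell_ids = fm$cell_ids, feature_names = fm$feature_names[j],
         kinds = fm$kinds[j],
         raw = fm$raw[, j, drop = FALSE],
         standardized = fm$standardized[, j, drop = FALSE]),
    class = "feature_matrix")
}

.feature_index <- function(fm, features) {
  if (is.character(features)) {
    j <- match(features, fm$feature_names)
    if (anyNA(j))
      stop(sprintf("unknown feature(s): %s",
                   paste(features[is.na(j)], collapse = ", ")))
  } else {
    j <- as.integer(features)
    if (any(j < 1L | j > length(fm$feature_names)))
      stop("feature index out of range")
  }
  j
}
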