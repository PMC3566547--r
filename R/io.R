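#' Read a cells-by-features table
#'
#' Reads a CSV or TSV table (delimiter sniffed from the header line), first
#' column cell ID, header row of feature names. A non-numeric or missing
#' entry is a hard error naming the offending cell and feature; ragged rows
#' are rejected by the underlying reader.
#'
#' @param path file path.
#' @return numeric matrix with cell ids as row names.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs a cell-id column plus >= 1 feature")
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(vals)))
  nas <- which(is.na(num), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    i <- nas[1L, 1L]; j <- nas[1L, 2L]
    stop(sprintf("non-numeric or missing value '%s' for cell '%s', feature '%s'",
                 vals[i, j], ids[i], colnames(vals)[j]))
  }
  rownames(num) <- ids
  num
}

#' Read a feature-metadata file
#'
#' CSV with columns `feature_name` and `kind` (`continuous` or `boolean`).
#'
#' @param path file path.
#' @return data frame with columns `feature_name`, `kind`.
#' @export
read_feature_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: %s", path))
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("feature_name", "kind")
  if (!all(need %in% names(meta)))
    stop("metadata file must have columns 'feature_name' and 'kind'")
  if (!all(meta$kind %in% c("continuous", "boolean")))
    stop("unknown kind in metadata; use 'continuous' or 'boolean'")
  meta[, need]
}

#' Assemble a feature matrix from table + metadata files
#' @param table_path path to the cells-by-features CSV/TSV.
#' @param meta_path path to the feature-metadata CSV.
#' @return a [feature_matrix()].
#' @export
load_feature_matrix <- function(table_path, meta_path) {
  tab <- read_feature_table(table_path)
  meta <- read_feature_meta(meta_path)
  missing <- setdiff(colnames(tab), meta$feature_name)
  if (length(missing))
    stop(sprintf("features missing from metadata: %s",
                 paste(missing, collapse = ", ")))
  kinds <- meta$kind[match(colnames(tab), meta$feature_name)]
  feature_matrix(tab, kinds)
}

# write a data frame as CSV with full double precision (>= 15 significant
# digits), atomically (write to tmp then rename)
.write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  old <- options(digits = 15); on.exit(options(old))
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a fitted partition to a directory
#'
#' Writes `memberships.csv` (cells x clusters, rows sum to 1),
#' `centroids.csv` and a `manifest.json` echoing the configuration, seeds,
#' effective cluster count, cost, iteration count and coalescence log --
#' sufficient to reproduce the fit.
#'
#' @param partition a `fuzzy_partition`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- as.data.frame(partition$memberships)
  names(M) <- paste0("cluster_", seq_len(ncol(M)))
  M <- cbind(cell_id = rownames(partition$memberships), M)
  .write_csv_atomic(M, file.path(dir, "memberships.csv"))
  U <- as.data.frame(partition$centroids)
  U <- cbind(cluster = paste0("cluster_", seq_len(nrow(U))), U)
  .write_csv_atomic(U, file.path(dir, "centroids.csv"))
  manifest <- list(
    software = paste0("fuzzyarchetypes ",
                      as.character(utils::packageVersion("fuzzyarchetypes"))),
    mu = partition$mu, c_effective = partition$c_effective,
    cost = partition$cost, n_iterations = partition$n_iterations,
    converged = partition$converged,
    coalescence_log = partition$coalescence_log,
    config = unclass(partition$config),
    init_indices = partition$init_indices,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a partition directory written by [write_partition()]
#' @param dir directory containing `memberships.csv`, `centroids.csv`,
#'   `manifest.json`.
#' @return a `fuzzy_partition`.
#' @export
read_partition <- function(dir) {
  mpath <- file.path(dir, "memberships.csv")
  if (!file.exists(mpath)) stop(sprintf("no memberships.csv in %s", dir))
  mem <- read.csv(mpath, check.names = FALSE)
  M <- as.matrix(mem[, -1L, drop = FALSE])
  rownames(M) <- mem[[1L]]
  U <- as.matrix(read.csv(file.path(dir, "centroids.csv"),
                          check.names = FALSE)[, -1L, drop = FALSE])
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(
    list(centroids = U, memberships = M, mu = man$mu, cost = man$cost,
         cost_trace = NULL, n_iterations = man$n_iterations,
         converged = man$converged,
         coalescence_log = man$coalescence_log,
         c_effective = man$c_effective,
         init_indices = man$init_indices, config = man$config),
    class = "fuzzy_partition")
}
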