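#' Read a sample matrix from delimited text
#'
#' Reads a numeric matrix (rows = observations) from a CSV or TSV file. The
#' delimiter is taken from the extension (`.tsv`/`.txt` tab, otherwise comma)
#' unless given. A single leading non-numeric line is treated as a header.
#' Ragged rows and non-numeric cells raise errors naming the offending row and
#' column.
#'
#' @param path file path.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return numeric matrix.
#' @export
read_sample_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("input file is empty: ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- suppressWarnings(any(is.na(as.numeric(trimws(cells[[1]])))))
  if (header) {
    cells <- cells[-1]
    if (length(cells) == 0) stop("input file has a header but no data: ", path)
  }
  ncol <- length(cells[[1]])
  nper <- lengths(cells)
  if (any(nper != ncol))
    stop(sprintf("ragged input: row %d has %d fields, expected %d",
                 which(nper != ncol)[1] + header, nper[nper != ncol][1], ncol))
  m <- matrix(NA_real_, length(cells), ncol)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at row %d, column %d",
                   trimws(cells[[i]][j]), i + header, j))
    }
    m[i, ] <- v
  }
  if (!all(is.finite(m))) stop("input contains non-finite values: ", path)
  m
}

#' Write a sample matrix as delimited text
#'
#' @param x numeric matrix or vector.
#' @param path output path; extension selects the delimiter as in
#'   [read_sample_matrix()].
#' @param sep field separator; `NULL` to infer from the extension.
#' @export
write_sample_matrix <- function(x, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  x <- as_sample_matrix(x)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize an MGC test result to JSON
#'
#' Writes statistic, p-value, optimal scales (1-based), threshold, region
#' size, permutation count, seed and configuration at full precision.
#'
#' @param result an object from [mgc_test()].
#' @param path output path.
#' @export
write_mgc_json <- function(result, path) {
  stopifnot(inherits(result, "mgc_test"))
  obj <- list(
    statistic = result$statistic,
    p_value = result$p_value,
    optimal_scales = lapply(seq_len(nrow(result$optimal_scales)), function(i)
      as.integer(result$optimal_scales[i, ])),
    scale = as.integer(result$scale),
    tau = result$tau,
    region_size = as.integer(result$region_size),
    smoothed = result$smoothed,
    n = as.integer(result$n),
    reps = as.integer(result$reps),
    seed = if (is.null(result$seed)) NULL else as.integer(result$seed),
    metric = result$metric,
    scheme = result$scheme
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back an MGC result written by [write_mgc_json()]
#' @param path JSON file path.
#' @return named list of result fields.
#' @export
read_mgc_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a local-correlation map as TSV
#'
#' Writes the n x n map with 1-based scale indices as column header
#' (`l1..ln`).
#'
#' @param cmap local-correlation map matrix.
#' @param path output path.
#' @export
write_map_tsv <- function(cmap, path) {
  colnames(cmap) <- paste0("l", seq_len(ncol(cmap)))
  utils::write.table(cmap, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded CSV fixture pairs
#'
#' Writes a deterministic pair of sample files used by the test suite and as
#' quick-start inputs for the command-line tool.
#'
#' @param kind one of `"linear_exact"` (noiseless affine pair, n = 20),
#'   `"spiral"` (noisy 1-D spiral, n = 60), `"independent"` (multimodal
#'   independence, n = 100), `"tiny_random"` (independent Gaussians, n = 10).
#' @param seed integer seed.
#' @param dir output directory.
#' @return character vector of the two file paths (x, y).
#' @export
make_fixture <- function(kind = c("linear_exact", "spiral", "independent",
                                  "tiny_random"),
                         seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  set.seed(seed)
  d <- switch(kind,
    linear_exact = {
      x <- matrix(stats::runif(20, -1, 1), ncol = 1)
      list(x = x, y = 2 * x + 3)
    },
    spiral = simulate_relationship(8, n = 60, p = 1, kappa = 1),
    independent = simulate_relationship(20, n = 100, p = 1),
    tiny_random = list(x = matrix(stats::rnorm(20), 10, 2),
                       y = matrix(stats::rnorm(20), 10, 2))
  )
  paths <- file.path(dir, paste0(kind, "_", c("x", "y"), ".csv"))
  write_sample_matrix(d$x, paths[1])
  write_sample_matrix(d$y, paths[2])
  paths
}
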