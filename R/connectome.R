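#' Directed weighted connectome
#'
#' A square non-negative coupling matrix (rows = target region, columns =
#' source region) with unique region labels and optional conduction delays.
#'
#' @param weights n x n non-negative numeric matrix
#' @param labels character vector of n unique region names
#' @param delays optional n x n delay matrix (ms)
#' @return an object of class `connectome`
#' @export
connectome <- function(weights, labels, delays = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 2 || ncol(weights) != n) stop("weights must be square with n >= 2")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be n unique region names")
  if (!is.null(delays)) {
    delays <- as.matrix(delays)
    if (!all(dim(delays) == n) || any(!is.finite(delays)) || any(delays < 0))
      stop("delays must be a finite non-negative n x n matrix")
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, delays = delays, n = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", x$n, "regions,",
      sum(x$weights > 0), "directed edges",
      if (is.null(x$delays)) "(no delays)\n" else "(with delays)\n")
  invisible(x)
}

#' Read / write a connectome as CSV plus a sidecar label list
#'
#' The matrix file is a headerless CSV of the square weight matrix; the
#' sidecar holds one region label per line.
#'
#' @param matrix_path path to the CSV weight matrix
#' @param labels_path path to the label list (one label per line)
#' @return for the reader, a [connectome()] object
#' @export
read_connectome <- function(matrix_path, labels_path) {
  w <- as.matrix(read.table(matrix_path, sep = ",", header = FALSE))
  labels <- readLines(labels_path)
  connectome(unname(w), labels)
}

#' @rdname read_connectome
#' @param conn a [connectome()] object
#' @export
write_connectome <- function(conn, matrix_path, labels_path) {
  write.table(conn$weights, matrix_path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(conn$labels, labels_path)
  invisible(matrix_path)
}

#' Near-square 2D layout for region statistics maps
#'
#' Deterministically assigns each region a cell on a near-square integer
#' grid, row-major in label order, for 2D rendering of per-region maps.
#'
#' @param labels character vector of unique region labels
#' @return data frame with columns `label`, `row`, `col` (1-based)
#' @export
grid_layout <- function(labels) {
  if (anyDuplicated(labels)) stop("labels must be unique")
  n <- length(labels)
  ncol <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  data.frame(label = as.character(labels),
             row = idx %/% ncol + 1L,
             col = idx %% ncol + 1L,
             stringsAsFactors = FALSE)
}
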