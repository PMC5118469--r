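#' Column-centered dataset container
#'
#' A `data_block` holds one dataset's samples-by-features matrix after
#' column centering, together with the removed column means. All model
#' fitting operates on centered data; the recorded means are reused to
#' center held-out data honestly at prediction time.
#'
#' @param values Numeric matrix (or object coercible to one), rows =
#'   samples, columns = features. Must have at least 2 rows and only finite
#'   entries.
#'
#' @return An object of class `data_block` with fields `values` (the
#'   centered matrix) and `column_means`.
#' @examples
#' b <- data_block(matrix(rnorm(20), 5, 4))
#' colMeans(b$values)  # ~ 0
#' @export
data_block <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2)
    stop("a data block needs at least 2 rows (samples); got ", nrow(values),
         call. = FALSE)
  bad <- which(!apply(values, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite entries in data block at row ", bad[1L], call. = FALSE)
  mu <- colMeans(values)
  structure(
    list(values = sweep(values, 2L, mu, "-"), column_means = mu),
    class = "data_block"
  )
}

#' @rdname data_block
#' @param x Object to coerce.
#' @export
as_data_block <- function(x) {
  if (inherits(x, "data_block")) x else data_block(x)
}

#' Recover the raw (uncentered) matrix of a block
#' @noRd
raw_values <- function(block) {
  if (inherits(block, "data_block"))
    sweep(block$values, 2L, block$column_means, "+")
  else {
    x <- as.matrix(block)
    storage.mode(x) <- "double"
    x
  }
}

#' @export
print.data_block <- function(x, ...) {
  cat("<data_block> ", nrow(x$values), " samples x ", ncol(x$values),
      " features (column-centered)\n", sep = "")
  invisible(x)
}

#' Split a dataset into first-half training and second-half test sets
#'
#' Rows are split in order: the first `floor(n/2)` rows become the training
#' set and the remainder the test set, matching the usual chronological
#' train/test split for timeseries.
#'
#' @param block A `data_block` or numeric matrix.
#' @return List with elements `train` and `test`: raw (uncentered) numeric
#'   matrices whose rows, stacked, reproduce the input exactly. Centering is
#'   deferred to [fit_cca()] so that each half is centered on its own
#'   training statistics.
#' @examples
#' s <- split_halves(matrix(rnorm(14), 7, 2))
#' nrow(s$train)  # 3
#' nrow(s$test)   # 4
#' @export
split_halves <- function(block) {
  x <- raw_values(block)
  n <- nrow(x)
  if (n < 2)
    stop("cannot split a dataset with fewer than 2 rows", call. = FALSE)
  h <- n %/% 2L
  list(train = x[seq_len(h), , drop = FALSE],
       test  = x[(h + 1L):n, , drop = FALSE])
}
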