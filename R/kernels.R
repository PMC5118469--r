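#' Kernel specification for dual-mode CCA
#'
#' @param ktype Kernel type: `"linear"` (inner product), `"gaussian"`
#'   (radial basis, `exp(-||x - y||^2 / (2 * gausigma^2))`), or `"poly"`
#'   (homogeneous polynomial, `(x . y)^degree`, no additive offset).
#' @param gausigma Positive Gaussian width; default 1.
#' @param degree Integer polynomial degree >= 1; default 2.
#'
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(ktype = c("linear", "gaussian", "poly"),
                        gausigma = 1.0, degree = 2L) {
  ktype <- match.arg(ktype)
  if (!is.finite(gausigma) || gausigma <= 0)
    stop("gausigma must be a positive scalar", call. = FALSE)
  if (!is.finite(degree) || degree != as.integer(degree) || degree < 1)
    stop("degree must be an integer >= 1", call. = FALSE)
  structure(list(ktype = ktype, gausigma = gausigma,
                 degree = as.integer(degree)),
            class = "kernel_spec")
}

#' Gram matrix of a dataset under a kernel
#'
#' Evaluates the kernel between all sample pairs of a (column-centered)
#' dataset. The result is symmetrized by averaging with its transpose to
#' remove floating-point asymmetry. No double-centering of the Gram and no
#' trace or `1/n` normalization is applied: data are column-centered before
#' kernel evaluation, and cross-products stay on the raw scale so that
#' regularization coefficients keep a consistent meaning between primal and
#' dual mode.
#'
#' @param block A `data_block` (its centered values are used) or a numeric
#'   matrix, which is taken as already centered and used as-is.
#' @param spec A [kernel_spec()].
#' @return Object of class `gram_matrix` with fields `values` (n-by-n
#'   symmetric matrix) and `source_shape`.
#' @examples
#' make_gram(diag(2), kernel_spec("linear"))$values  # identity
#' @export
make_gram <- function(block, spec = kernel_spec("linear")) {
  if (!inherits(spec, "kernel_spec"))
    stop("spec must be created by kernel_spec()", call. = FALSE)
  X <- if (inherits(block, "data_block")) block$values else {
    x <- as.matrix(block)
    storage.mode(x) <- "double"
    x
  }
  bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite entries in data block at row ", bad[1L], call. = FALSE)
  ip <- tcrossprod(X)
  G <- switch(spec$ktype,
    linear = ip,
    poly = ip ^ spec$degree,
    gaussian = {
      sq <- rowSums(X ^ 2)
      d2 <- outer(sq, sq, "+") - 2 * ip
      d2[d2 < 0] <- 0  # clip negative round-off distances
      exp(-d2 / (2 * spec$gausigma ^ 2))
    })
  G <- (G + t(G)) / 2
  structure(list(values = G, source_shape = dim(X)), class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat("<gram_matrix> ", nrow(x$values), " x ", ncol(x$values),
      " from a ", x$source_shape[1], " x ", x$source_shape[2],
      " block\n", sep = "")
  invisible(x)
}
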