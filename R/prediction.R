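#' Spectral-cutoff regularized pseudoinverse
#'
#' Moore-Penrose pseudoinverse computed by singular value decomposition in
#' which singular values below `cutoff` times the largest singular value are
#' zeroed before reconstruction. `cutoff = 0` gives the plain pseudoinverse
#' (singular values below machine-precision scale are still dropped, as in
#' any numerical pseudoinverse).
#'
#' @param W Numeric matrix.
#' @param cutoff Relative truncation threshold in `[0, 1)`.
#' @return The (possibly truncated) pseudoinverse of `W`.
#' @examples
#' regularized_pinv(diag(c(2, 1)))               # diag(0.5, 1)
#' regularized_pinv(diag(c(10, 0.5)), cutoff = 0.1)  # second value dropped
#' @export
regularized_pinv <- function(W, cutoff = 0) {
  W <- as.matrix(W)
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff < 0 || cutoff >= 1)
    stop("cutoff must lie in [0, 1)", call. = FALSE)
  if (all(W == 0)) {
    warning("all-zero matrix: pseudoinverse is the zero matrix",
            call. = FALSE)
    return(t(W))
  }
  sv <- svd(W)
  dmax <- max(sv$d)
  thresh <- max(cutoff * dmax,
                dmax * .Machine$double.eps * max(dim(W)))
  dinv <- ifelse(sv$d >= thresh & sv$d > 0, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Cross-dataset prediction of held-out data
#'
#' Predicts each held-out dataset from the others through the shared
#' canonical space: every other dataset is projected onto its canonical
#' weights, the projections are averaged, and the average is mapped back
#' into the target dataset's feature space through the (spectral-cutoff)
#' pseudoinverse of the target's weights. For two datasets this is
#' `predicted = pinv(b')' u` with `u = a' x_novel`. Prediction accuracy is
#' the per-feature Pearson correlation between predicted and actual
#' held-out columns.
#'
#' Held-out data are centered with the *training* means stored in the
#' model, so the prediction is honestly out-of-sample; Pearson correlation
#' itself is shift-invariant, so `corrs` do not depend on this choice, but
#' the absolute scale of `preds` does.
#'
#' @param model A fitted `cca_model`.
#' @param test_blocks List of held-out matrices/`data_block`s in the same
#'   order as at training, with matching feature counts.
#' @param cutoff Spectral-cutoff threshold for the pseudoinverse
#'   (default 0).
#' @return Object of class `prediction_result` with `preds` (list of
#'   centered predicted matrices) and `corrs` (list of per-feature
#'   correlation vectors). A zero-variance column is recorded as 0 with a
#'   warning.
#' @export
predict_heldout <- function(model, test_blocks, cutoff = 0) {
  stopifnot(inherits(model, "cca_model"))
  if (!is.list(test_blocks) || length(test_blocks) < 2)
    stop("cross-dataset prediction needs at least 2 datasets", call. = FALSE)
  if (length(test_blocks) != length(model$weights))
    stop("expected ", length(model$weights), " datasets (as at training), ",
         "got ", length(test_blocks), call. = FALSE)
  X <- center_with_training(model, test_blocks)
  U <- Map(function(x, w) x %*% w, X, model$weights)
  nb <- length(X)
  preds <- vector("list", nb)
  corrs <- vector("list", nb)
  for (i in seq_len(nb)) {
    Ubar <- Reduce(`+`, U[-i]) / (nb - 1)
    preds[[i]] <- Ubar %*% t(regularized_pinv(t(model$weights[[i]]), cutoff))
    corrs[[i]] <- vapply(seq_len(ncol(preds[[i]])), function(f)
      safe_cor(preds[[i]][, f], X[[i]][, f], what = "held-out feature"),
      numeric(1))
  }
  structure(list(preds = preds, corrs = corrs), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  r <- unlist(x$corrs)
  cat("<prediction_result> ", length(x$preds), " datasets, ",
      length(r), " features; corr range [",
      sprintf("%.3f", min(r)), ", ", sprintf("%.3f", max(r)), "]\n",
      sep = "")
  invisible(x)
}

# center held-out blocks with the model's training means
center_with_training <- function(model, test_blocks) {
  Map(function(b, mu) {
    x <- raw_values(b)
    if (ncol(x) != length(mu))
      stop("feature count (", ncol(x), ") does not match training (",
           length(mu), ")", call. = FALSE)
    sweep(x, 2L, mu, "-")
  }, test_blocks, model$training_means)
}

#' Variance explained per canonical component in held-out data
#'
#' For each dataset and each canonical component, the component timeseries
#' is formed from the held-out data and the component's explained-variance
#' fraction for each feature column is the squared Pearson correlation
#' between that timeseries and the column — the R-squared of the best
#' single-regressor linear fit.
#'
#' @inheritParams predict_heldout
#' @return Object of class `ev_result`: `ev` is a list of
#'   `n_components`-by-`n_features` matrices with entries in `[0, 1]`.
#'   A zero-variance component yields a zero row with a warning.
#' @export
explained_variance <- function(model, test_blocks) {
  stopifnot(inherits(model, "cca_model"))
  if (length(test_blocks) != length(model$weights))
    stop("expected ", length(model$weights), " datasets (as at training), ",
         "got ", length(test_blocks), call. = FALSE)
  X <- center_with_training(model, test_blocks)
  ev <- Map(function(x, w) {
    U <- x %*% w
    out <- matrix(0, ncol(U), ncol(x))
    for (k in seq_len(ncol(U)))
      for (f in seq_len(ncol(x)))
        out[k, f] <- safe_cor(U[, k], x[, f], what = "component")^2
    out
  }, X, model$weights)
  structure(list(ev = ev), class = "ev_result")
}

#' Asymptotic significance of prediction correlations with FDR control
#'
#' Each correlation is Fisher z-transformed, `z = atanh(r) * sqrt(n - 3)`,
#' and referred to the standard normal for a two-sided p-value; the
#' Benjamini-Hochberg step-up procedure at level `alpha` then yields the
#' set of significantly predicted features. Correlations at exactly +/-1
#' are clamped to `1 - 1e-15` in magnitude before the transform.
#'
#' @param corrs Numeric vector of per-feature prediction correlations.
#' @param n_test Number of held-out samples the correlations were computed
#'   from (must be at least 4).
#' @param alpha FDR level in (0, 1); default 0.05.
#' @return Object of class `significance_result`: `p_values`,
#'   `q_threshold` (the adaptive BH cutoff on the raw p-value scale; 0 when
#'   nothing is significant) and `significant_mask`.
#' @examples
#' prediction_significance(c(0, 0.5, 0.9), n_test = 100)
#' @export
prediction_significance <- function(corrs, n_test, alpha = 0.05) {
  corrs <- as.numeric(corrs)
  if (!length(corrs)) stop("corrs is empty", call. = FALSE)
  if (any(!is.finite(corrs)) || any(abs(corrs) > 1))
    stop("corrs must be finite correlations in [-1, 1]", call. = FALSE)
  if (length(n_test) != 1 || n_test < 4)
    stop("n_test must be at least 4", call. = FALSE)
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  r <- pmin(pmax(corrs, -1 + 1e-15), 1 - 1e-15)
  z <- atanh(r) * sqrt(n_test - 3)
  p <- 2 * pnorm(-abs(z))
  mask <- p.adjust(p, method = "BH") <= alpha
  structure(
    list(p_values = p,
         q_threshold = if (any(mask)) max(p[mask]) else 0,
         significant_mask = mask),
    class = "significance_result"
  )
}
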