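#' Configuration for Monte-Carlo block cross-validation
#'
#' Defaults follow common practice for timeseries CCA: candidate
#' regularization coefficients are 10 log-spaced values in `[1e-3, 10]`,
#' candidate component counts 5 to 10, 10 Monte-Carlo iterations each
#' holding out 20% of the samples in contiguous blocks of 10 (contiguous
#' blocks respect temporal autocorrelation), and scoring by the mean of the
#' best-predicted top 20% of feature dimensions.
#'
#' @param regs Numeric vector of candidate regularization coefficients.
#' @param numCCs Integer vector of candidate component counts.
#' @param numCV Number of Monte-Carlo iterations (default 10).
#' @param select Fraction in (0, 1] of best-predicted feature dimensions
#'   averaged by the accuracy metric (default 0.2).
#' @param holdout_fraction Fraction of samples held out per iteration
#'   (default 0.2).
#' @param block_length Length of each contiguous held-out block
#'   (default 10 samples).
#' @param cutoff Spectral-cutoff threshold used in CV predictions
#'   (default 0).
#' @param seed Integer seed; together with the iteration number it fully
#'   determines every split.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(regs = 10 ^ seq(-3, 1, length.out = 10),
                      numCCs = 5:10,
                      numCV = 10L,
                      select = 0.2,
                      holdout_fraction = 0.2,
                      block_length = 10L,
                      cutoff = 0,
                      seed = 1L) {
  if (!length(regs) || any(!is.finite(regs)) || any(regs < 0))
    stop("regs must be non-negative candidates", call. = FALSE)
  if (!length(numCCs) || any(numCCs < 1) || any(numCCs != as.integer(numCCs)))
    stop("numCCs must be positive integers", call. = FALSE)
  if (numCV < 1) stop("numCV must be >= 1", call. = FALSE)
  if (select <= 0 || select > 1) stop("select must lie in (0, 1]", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  if (block_length < 1) stop("block_length must be >= 1", call. = FALSE)
  structure(
    list(regs = as.numeric(regs), numCCs = as.integer(numCCs),
         numCV = as.integer(numCV), select = select,
         holdout_fraction = holdout_fraction,
         block_length = as.integer(block_length),
         cutoff = cutoff, seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' One Monte-Carlo block holdout split
#'
#' Holds out `floor(holdout_fraction * n / block_length)` disjoint,
#' contiguous blocks of `block_length` consecutive samples whose start
#' offsets are aligned to multiples of `block_length` and drawn without
#' replacement. Remainder samples (when `n` is not a block multiple) stay
#' in the training split. The split is a deterministic function of
#' `(cfg$seed, iteration)`.
#'
#' @param n_samples Total sample count.
#' @param cfg A [cv_config()].
#' @param iteration Iteration number (1-based).
#' @return List with integer vectors `train` and `holdout`, a partition of
#'   `1:n_samples`.
#' @export
make_cv_split <- function(n_samples, cfg = cv_config(), iteration = 1L) {
  stopifnot(inherits(cfg, "cv_config"))
  b <- cfg$block_length
  n_chunks <- floor(cfg$holdout_fraction * n_samples / b)
  if (n_chunks < 1)
    stop("holdout_fraction * n_samples is below one block; ",
         "use a smaller block_length", call. = FALSE)
  n_avail <- n_samples %/% b
  starts <- with_seed(derive_seed(cfg$seed, iteration),
                      sample(n_avail, n_chunks)) - 1L
  holdout <- sort(as.integer(outer(seq_len(b), starts * b, "+")))
  list(train = setdiff(seq_len(n_samples), holdout), holdout = holdout)
}

#' Top-fraction prediction accuracy metric
#'
#' For each dataset, the per-feature prediction correlations are sorted and
#' the top `ceiling(select * p)` of them averaged; the metric is the mean of
#' these per-dataset averages. Focusing on the best-predicted fraction keeps
#' the score informative when many dimensions are noise.
#'
#' @param corrs_per_dataset List of per-feature correlation vectors (a bare
#'   numeric vector is treated as one dataset).
#' @param select Fraction in (0, 1] of dimensions to average (default 0.2).
#' @return Scalar accuracy.
#' @examples
#' select_metric(list(seq(0.1, 1, by = 0.1)), select = 0.2)  # 0.95
#' @export
select_metric <- function(corrs_per_dataset, select = 0.2) {
  if (is.numeric(corrs_per_dataset))
    corrs_per_dataset <- list(corrs_per_dataset)
  if (select <= 0 || select > 1) stop("select must lie in (0, 1]", call. = FALSE)
  if (any(!vapply(corrs_per_dataset, length, integer(1))))
    stop("empty correlation vector", call. = FALSE)
  mean(vapply(corrs_per_dataset, function(v) {
    k <- ceiling(select * length(v))
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }, numeric(1)))
}

#' Hyperparameter selection by Monte-Carlo block cross-validated grid search
#'
#' For every `(reg, numCC)` candidate pair and every CV iteration, a model
#' is fitted on the ~80% training split, the held-out blocks are predicted
#' across datasets, and the fit is scored with [select_metric()]. Scores are
#' averaged over iterations, the best pair is chosen (ties broken toward the
#' smallest `numCC`, then the largest `reg` — parsimony first, shrinkage
#' second), and a final model is refitted on all supplied data with the
#' winning pair. A candidate whose fit fails (for example `numCC` exceeding
#' a feature count) scores `-Inf` with a warning rather than aborting the
#' search.
#'
#' @param blocks List of datasets as in [fit_cca()].
#' @param cfg A [cv_config()].
#' @param kernel `NULL` (primal) or a [kernel_spec()].
#' @param verbose Logical; default follows `options(rkcca.verbose = )`.
#' @return Object of class `cv_result`: `score_grid` (regs-by-numCCs mean
#'   score matrix with dimnames), `best_reg`, `best_numCC`,
#'   `iteration_scores` (numCV x regs x numCCs array) and `model`, the
#'   final refit `cca_model`.
#' @examples
#' sim <- simulate_latent_data(synthetic_spec(n_samples = 300, seed = 3))
#' cfg <- cv_config(regs = c(0, 100), numCCs = 1:2, numCV = 2, seed = 3)
#' cv <- grid_search(sim$datasets, cfg, verbose = FALSE)
#' cv$best_numCC
#' @export
grid_search <- function(blocks, cfg = cv_config(), kernel = NULL,
                        verbose = NULL) {
  stopifnot(inherits(cfg, "cv_config"))
  blocks <- lapply(blocks, as_data_block)
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(ns)) != 1)
    stop("sample-count mismatch across datasets: ",
         paste(ns, collapse = ", "), call. = FALSE)
  n <- ns[1]
  raw <- lapply(blocks, raw_values)
  nr <- length(cfg$regs)
  nc <- length(cfg$numCCs)
  iter_scores <- array(NA_real_, dim = c(cfg$numCV, nr, nc))
  vmessage("Grid search: ", nr, " x ", nc, " candidates, ", cfg$numCV,
           " Monte-Carlo iterations", verbose = verbose)
  for (it in seq_len(cfg$numCV)) {
    sp <- make_cv_split(n, cfg, it)
    trn <- lapply(raw, function(x) x[sp$train, , drop = FALSE])
    hld <- lapply(raw, function(x) x[sp$holdout, , drop = FALSE])
    for (a in seq_len(nr)) {
      for (b in seq_len(nc)) {
        iter_scores[it, a, b] <- tryCatch({
          m <- fit_cca(trn, reg = cfg$regs[a],
                       n_components = cfg$numCCs[b],
                       kernel = kernel, verbose = FALSE)
          pr <- predict_heldout(m, hld, cutoff = cfg$cutoff)
          select_metric(pr$corrs, cfg$select)
        }, error = function(e) {
          warning("candidate (reg = ", cfg$regs[a], ", numCC = ",
                  cfg$numCCs[b], ") failed in iteration ", it, ": ",
                  conditionMessage(e), call. = FALSE)
          -Inf
        })
      }
    }
  }
  score_grid <- apply(iter_scores, c(2, 3), mean)
  dimnames(score_grid) <- list(reg = format(cfg$regs, trim = TRUE),
                               numCC = cfg$numCCs)
  top <- which(score_grid == max(score_grid), arr.ind = TRUE)
  top <- top[order(cfg$numCCs[top[, 2]], -cfg$regs[top[, 1]]), , drop = FALSE]
  best_reg <- cfg$regs[top[1, 1]]
  best_numCC <- cfg$numCCs[top[1, 2]]
  vmessage("Selected reg = ", best_reg, ", numCC = ", best_numCC,
           "; refitting on all data", verbose = verbose)
  model <- fit_cca(blocks, reg = best_reg, n_components = best_numCC,
                   kernel = kernel, verbose = FALSE)
  structure(
    list(score_grid = score_grid, best_reg = best_reg,
         best_numCC = best_numCC, iteration_scores = iter_scores,
         regs = cfg$regs, numCCs = cfg$numCCs, select = cfg$select,
         cutoff = cfg$cutoff, model = model),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> best reg = ", x$best_reg, ", best numCC = ",
      x$best_numCC, " (grid max score ", sprintf("%.4f", max(x$score_grid)),
      ")\n", sep = "")
  invisible(x)
}
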