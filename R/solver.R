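#' Assemble the block generalized eigensystem for (kernel) CCA
#'
#' For datasets \eqn{X_1, \dots, X_B} sharing a sample count, multi-set CCA
#' solves \eqn{A v = \rho B v} where the left-hand side `lhs` has zero
#' diagonal blocks and cross-product blocks \eqn{X_i' X_j} off the diagonal,
#' and the right-hand side `rhs` is block-diagonal with
#' \eqn{X_i' X_i + \lambda I}. In dual (kernel) mode the same layout is
#' built from Gram matrices: off-diagonal \eqn{K_i K_j}, diagonal
#' \eqn{K_i^2 + \lambda I}. Cross-products are raw (not divided by n or
#' n-1), so `reg` is on the scale of summed, not averaged, products.
#'
#' Both sides are explicitly symmetrized by averaging with their transposes
#' to remove floating-point asymmetry.
#'
#' @param blocks List (length >= 2) of `data_block`s / numeric matrices
#'   (primal mode) or of `gram_matrix` objects (dual mode). Mixing modes is
#'   an error.
#' @param reg Non-negative regularization coefficient \eqn{\lambda}.
#' @return Object of class `eigensystem`: `lhs`, `rhs`, `block_dims`
#'   (per-block segment widths), `mode` ("primal" or "dual") and `reg`.
#' @export
build_eigensystem <- function(blocks, reg = 0) {
  if (!is.list(blocks) || length(blocks) < 2)
    stop("need at least 2 blocks", call. = FALSE)
  if (length(reg) != 1 || !is.finite(reg) || reg < 0)
    stop("reg must be a non-negative scalar", call. = FALSE)
  dual <- vapply(blocks, inherits, logical(1), what = "gram_matrix")
  if (any(dual) && !all(dual))
    stop("cannot mix data blocks and Gram matrices", call. = FALSE)
  dual <- all(dual)
  mats <- if (dual) lapply(blocks, `[[`, "values")
          else lapply(lapply(blocks, as_data_block), `[[`, "values")
  ns <- if (dual) vapply(mats, nrow, integer(1))
        else vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("sample-count mismatch across blocks: ",
         paste(ns, collapse = ", "), call. = FALSE)
  p <- vapply(mats, ncol, integer(1))  # in dual mode, ncol == n
  off <- c(0L, cumsum(p))
  tot <- sum(p)
  lhs <- matrix(0, tot, tot)
  rhs <- matrix(0, tot, tot)
  for (i in seq_along(mats)) {
    ii <- (off[i] + 1L):off[i + 1L]
    for (j in seq_along(mats)) {
      jj <- (off[j] + 1L):off[j + 1L]
      C <- if (dual) mats[[i]] %*% mats[[j]] else crossprod(mats[[i]], mats[[j]])
      if (i == j) rhs[ii, jj] <- C + diag(reg, p[i]) else lhs[ii, jj] <- C
    }
  }
  lhs <- (lhs + t(lhs)) / 2
  rhs <- (rhs + t(rhs)) / 2
  structure(list(lhs = lhs, rhs = rhs, block_dims = p,
                 mode = if (dual) "dual" else "primal", reg = reg),
            class = "eigensystem")
}

#' Solve the symmetric-definite generalized eigenproblem
#'
#' Whitening route: the right-hand side is eigendecomposed, directions whose
#' eigenvalue falls below `1e-12` of the largest are dropped (they carry no
#' data variance), and the problem is reduced to a standard symmetric
#' eigendecomposition in the whitened basis. Eigenpairs are returned sorted
#' by descending eigenvalue; the top `n_components` eigenvectors are split
#' row-wise into per-block weight segments. For two blocks the spectrum
#' comes in +/- pairs and only the non-negative branch survives the sort.
#'
#' When the system was built with `reg = 0`, a tiny ridge (`1e-8` times the
#' mean diagonal of the right-hand side) is added purely for numerical
#' solvability; a status message notes this.
#'
#' The sign of each eigenvector is fixed by making the largest-magnitude
#' entry of its first-block segment positive (canonical weights are
#' sign-ambiguous).
#'
#' @param es An `eigensystem` from [build_eigensystem()].
#' @param n_components Number of leading eigenvectors to keep.
#' @param verbose Logical; default follows `options(rkcca.verbose = )`.
#' @return List with `weights` (per-block segment matrices, one column per
#'   component) and `eigenvalues` (the kept leading eigenvalues).
#' @export
solve_eigensystem <- function(es, n_components, verbose = NULL) {
  stopifnot(inherits(es, "eigensystem"))
  tot <- sum(es$block_dims)
  if (length(n_components) != 1 || n_components < 1 || n_components > tot)
    stop("n_components must be between 1 and ", tot, call. = FALSE)
  n_components <- as.integer(n_components)
  rhs <- es$rhs
  if (es$reg == 0) {
    jit <- 1e-8 * mean(diag(rhs))
    if (!is.finite(jit) || jit <= 0) jit <- 1e-12
    rhs <- rhs + diag(jit, tot)
    vmessage("reg = 0: adding tiny ridge (", format(jit, digits = 3),
             ") to the right-hand side for numerical solvability",
             verbose = verbose)
  }
  eB <- eigen(rhs, symmetric = TRUE)
  if (max(eB$values) <= 0)
    stop("right-hand side is numerically singular; refit with reg > 0",
         call. = FALSE)
  keep <- eB$values > max(eB$values) * 1e-12
  if (sum(keep) < n_components)
    stop("right-hand side rank (", sum(keep), ") is below n_components (",
         n_components, "); refit with reg > 0", call. = FALSE)
  W <- eB$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eB$values[keep]), sum(keep))
  M <- crossprod(W, es$lhs %*% W)
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)  # LAPACK: eigenvalues already descending
  V <- W %*% eM$vectors[, seq_len(n_components), drop = FALSE]
  seg1 <- seq_len(es$block_dims[1])
  for (k in seq_len(n_components)) {
    lead <- which.max(abs(V[seg1, k]))
    if (V[seg1[lead], k] < 0) V[, k] <- -V[, k]
  }
  off <- c(0L, cumsum(es$block_dims))
  weights <- lapply(seq_along(es$block_dims), function(i)
    V[(off[i] + 1L):off[i + 1L], , drop = FALSE])
  list(weights = weights, eigenvalues = eM$values[seq_len(n_components)])
}

#' Canonical correlations of fitted components
#'
#' For each component index, the Pearson correlation of the paired component
#' timeseries is averaged over all dataset pairs; for two datasets this is
#' the plain pairwise correlation. A zero-variance component column
#' contributes 0 to the mean, with a warning.
#'
#' @param components List of n-by-k component matrices, one per dataset,
#'   all of the same shape.
#' @return Numeric vector of length k.
#' @export
canonical_correlations <- function(components) {
  if (!is.list(components) || length(components) < 2)
    stop("need components from at least 2 datasets", call. = FALSE)
  dims <- lapply(components, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    stop("component matrices must share the same shape", call. = FALSE)
  k <- ncol(components[[1]])
  pairs <- utils::combn(length(components), 2)
  vapply(seq_len(k), function(j) {
    mean(apply(pairs, 2, function(pr)
      safe_cor(components[[pr[1]]][, j], components[[pr[2]]][, j],
               what = "component")))
  }, numeric(1))
}

#' Fit canonical correlation analysis across two or more datasets
#'
#' Centers each dataset, builds the (optionally kernelized) regularized
#' block eigensystem, solves it, and packages canonical weights, components
#' and correlations. In dual mode the dual coefficients `alpha` are
#' converted to feature-space weights `w = X' alpha`, so components and
#' downstream prediction always operate in feature space.
#'
#' @param blocks List (length >= 2) of numeric matrices or `data_block`s
#'   sharing a sample count.
#' @param reg Regularization coefficient \eqn{\lambda \ge 0} (default 0,
#'   none). Note the raw cross-product scale: useful values grow with the
#'   number of samples.
#' @param n_components Number of canonical components to keep (default 10,
#'   capped by the problem: at most the smallest feature count in primal
#'   mode).
#' @param kernel `NULL` for primal (covariance) mode, or a [kernel_spec()]
#'   for dual mode. Kernelization with `reg = 0` triggers a warning: for
#'   invertible kernels the unregularized problem admits a trivial,
#'   uninformative solution.
#' @param verbose Logical; default follows `options(rkcca.verbose = )`.
#'
#' @return Object of class `cca_model` with fields `reg`, `n_components`,
#'   `kernel`, `weights`, `components`, `cancorrs`, `training_means` and
#'   `eigenvalues`.
#' @examples
#' sim <- simulate_latent_data(synthetic_spec(n_samples = 400, seed = 1))
#' m <- fit_cca(sim$datasets, reg = 0, n_components = 2, verbose = FALSE)
#' round(m$cancorrs, 2)
#' @export
fit_cca <- function(blocks, reg = 0, n_components = 10L, kernel = NULL,
                    verbose = NULL) {
  if (!is.list(blocks) || length(blocks) < 2)
    stop("need at least 2 datasets", call. = FALSE)
  blocks <- lapply(blocks, as_data_block)
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(ns)) != 1)
    stop("sample-count mismatch across datasets: ",
         paste(ns, collapse = ", "), call. = FALSE)
  p <- vapply(blocks, function(b) ncol(b$values), integer(1))
  if (is.null(kernel)) {
    if (n_components > min(p))
      stop("n_components (", n_components, ") exceeds the smallest feature ",
           "count (", min(p), "); at most min(m, n) components exist",
           call. = FALSE)
    vmessage("Fitting primal CCA: ", length(blocks), " datasets, reg = ",
             reg, ", ", n_components, " components", verbose = verbose)
    es <- build_eigensystem(blocks, reg)
  } else {
    if (!inherits(kernel, "kernel_spec"))
      stop("kernel must be NULL or a kernel_spec()", call. = FALSE)
    if (reg == 0)
      warning("kernel CCA with reg = 0 admits a trivial solution for ",
              "invertible kernels; consider reg > 0", call. = FALSE)
    vmessage("Fitting kernel CCA (", kernel$ktype, "): ", length(blocks),
             " datasets, reg = ", reg, ", ", n_components, " components",
             verbose = verbose)
    grams <- lapply(blocks, make_gram, spec = kernel)
    es <- build_eigensystem(grams, reg)
  }
  sol <- solve_eigensystem(es, n_components, verbose = verbose)
  weights <- if (is.null(kernel)) sol$weights
             else Map(function(b, a) crossprod(b$values, a), blocks,
                      sol$weights)
  components <- Map(function(b, w) b$values %*% w, blocks, weights)
  structure(
    list(reg = reg,
         n_components = as.integer(n_components),
         kernel = kernel,
         weights = weights,
         components = components,
         cancorrs = canonical_correlations(components),
         training_means = lapply(blocks, `[[`, "column_means"),
         eigenvalues = sol$eigenvalues),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model> ", length(x$weights), " datasets, ", x$n_components,
      " components, reg = ", x$reg,
      if (is.null(x$kernel)) ", primal" else
        paste0(", kernel = ", x$kernel$ktype),
      "\n  cancorrs: ", paste(sprintf("%.3f", x$cancorrs), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
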