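test_that("eigensystem layout matches an explicitly loop-built block matrix", {
  blocks <- random_blocks(1, n = 30, ps = c(4, 5, 3))
  reg <- 2.5
  es <- build_eigensystem(blocks, reg = reg)
  expect_identical(es$block_dims, c(4L, 5L, 3L))
  expect_identical(dim(es$lhs), c(12L, 12L))
  expect_identical(dim(es$rhs), c(12L, 12L))

  Xs <- lapply(blocks, function(x) sweep(x, 2, colMeans(x)))
  off <- c(0, 4, 9, 12)
  lhs <- matrix(0, 12, 12); rhs <- matrix(0, 12, 12)
  for (i in 1:3) for (j in 1:3) {
    blk <- t(Xs[[i]]) %*% Xs[[j]]
    ii <- (off[i] + 1):off[i + 1]; jj <- (off[j] + 1):off[j + 1]
    if (i == j) rhs[ii, jj] <- blk + diag(reg, ncol(Xs[[i]]))
    else lhs[ii, jj] <- blk
  }
  expect_equal(es$lhs, (lhs + t(lhs)) / 2, tolerance = 1e-12)
  expect_equal(es$rhs, (rhs + t(rhs)) / 2, tolerance = 1e-12)
  # zero diagonal blocks on the lhs
  expect_equal(es$lhs[1:4, 1:4], matrix(0, 4, 4))

  # identical inputs at reg 0: rhs = block-diag(X'X, X'X)
  es0 <- build_eigensystem(list(blocks[[1]], blocks[[1]]), reg = 0)
  C <- crossprod(Xs[[1]])
  expect_equal(es0$rhs[1:4, 1:4], C, tolerance = 1e-10)
  expect_equal(es0$rhs[5:8, 5:8], C, tolerance = 1e-10)

  expect_error(build_eigensystem(blocks[1]), "at least 2")
  expect_error(build_eigensystem(blocks, reg = -1), "non-negative")
  expect_error(
    build_eigensystem(list(matrix(rnorm(20), 10, 2),
                           matrix(rnorm(22), 11, 2))), "mismatch")
})

test_that("1-D CCA recovers the Pearson correlation exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(40)
    y <- 0.6 * x + rnorm(40)
    m <- fit_cca(list(cbind(x), cbind(y)), reg = 0, n_components = 1)
    expect_equal(abs(m$cancorrs), abs(cor(x, y)), tolerance = 1e-10)
  }
})

test_that("identical and independent datasets bracket the cancorr range", {
  X <- random_blocks(2, 50, 3)[[1]]
  m <- fit_cca(list(X, X), reg = 0, n_components = 3)
  expect_equal(m$cancorrs, rep(1, 3), tolerance = 1e-6)

  ind <- random_blocks(3, n = 1e4, ps = c(1, 1))
  m2 <- fit_cca(ind, reg = 0, n_components = 1)
  expect_lt(abs(m2$cancorrs), 0.05)
})

test_that("two-block eigenvalue spectra come in +/- pairs", {
  for (seed in 1:3) {
    blocks <- random_blocks(seed + 10, n = 25, ps = c(3, 3))
    es <- build_eigensystem(blocks, reg = 1)
    sol <- solve_eigensystem(es, n_components = 6)
    ev <- sol$eigenvalues
    expect_equal(sort(ev), sort(-ev), tolerance = 1e-8)
    expect_true(all(diff(ev) <= 1e-10))  # descending order
  }
})

test_that("benchmark fit recovers two strong components and two weak ones", {
  h <- benchmark_halves(seed = 101)
  m <- fit_cca(h$train, reg = 0, n_components = 4)
  expect_equal(m$cancorrs[1], 0.95, tolerance = 0.02)
  expect_equal(m$cancorrs[2], 0.95, tolerance = 0.02)
  expect_lt(m$cancorrs[3], 0.3)
  expect_lt(m$cancorrs[4], 0.2)
  expect_true(all(diff(m$cancorrs) <= 1e-6))        # sorted non-increasing
  expect_true(all(abs(m$cancorrs) <= 1 + 1e-8))
  # reconstruction identity: components = centered data x weights
  for (i in 1:2) {
    Xc <- scale(raw_values(h$train[[i]]), scale = FALSE)
    expect_equal(m$components[[i]], Xc %*% m$weights[[i]],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # the span of the first two components recovers the latent subspace
  # (individual components can rotate within it because the two leading
  # canonical correlations are nearly equal)
  lat_train <- h$latents[1:500, ]
  for (j in 1:2) {
    r2 <- summary(lm(lat_train[, j] ~ m$components[[1]][, 1:2]))$r.squared
    expect_gt(r2, 0.85)
  }
})

test_that("primal and linear-kernel dual fits agree at reg 0", {
  for (seed in 1:3) {
    blocks <- random_blocks(seed + 20, n = 60, ps = c(4, 3))
    mp <- fit_cca(blocks, reg = 0, n_components = 3)
    md <- suppressWarnings(
      fit_cca(blocks, reg = 0, n_components = 3,
              kernel = kernel_spec("linear")))
    expect_equal(mp$cancorrs, md$cancorrs, tolerance = 1e-6)
  }
})

test_that("cancorrs are invariant to positive rescaling of a dataset", {
  blocks <- random_blocks(30, n = 40, ps = c(3, 4))
  m1 <- fit_cca(blocks, reg = 0, n_components = 3)
  m2 <- fit_cca(list(blocks[[1]] * 17.3, blocks[[2]]), reg = 0,
                n_components = 3)
  expect_equal(m1$cancorrs, m2$cancorrs, tolerance = 1e-8)
})

test_that("within-set components are orthogonal at reg 0 and not at large reg", {
  h <- benchmark_halves(seed = 102)
  m <- fit_cca(h$train, reg = 0, n_components = 4)
  for (i in 1:2) {
    cc <- cor(m$components[[i]])
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  }
  # regularization relaxes the orthogonality constraint
  mr <- fit_cca(h$train, reg = 1e6, n_components = 4)
  offdiag <- abs(cor(mr$components[[1]])[upper.tri(diag(4))])
  expect_gt(max(offdiag), 1e-4)
})

test_that("the large-reg limit converges to the PLS singular-vector pair", {
  for (seed in 1:3) {
    blocks <- random_blocks(seed + 40, n = 50, ps = c(5, 4))
    Xs <- lapply(blocks, function(x) sweep(x, 2, colMeans(x)))
    sv <- svd(crossprod(Xs[[1]], Xs[[2]]))  # oracle: SVD of C_XY
    m <- fit_cca(blocks, reg = 1e10, n_components = 1)
    cos_a <- sum(m$weights[[1]] * sv$u[, 1]) /
      sqrt(sum(m$weights[[1]]^2) * sum(sv$u[, 1]^2))
    cos_b <- sum(m$weights[[2]] * sv$v[, 1]) /
      sqrt(sum(m$weights[[2]]^2) * sum(sv$v[, 1]^2))
    expect_gt(abs(cos_a), 0.99)
    expect_gt(abs(cos_b), 0.99)
  }
})

test_that("multi-set canonical correlations average over dataset pairs", {
  # constructed components with pairwise correlations 1.0, 0.5, 0.5
  set.seed(60)
  u <- rnorm(200)
  noise <- rnorm(200)
  # choose mix so that cor(u, w) = 0.5; w identical for sets 2 and 3
  w <- 0.5 / sqrt(1 - 0.5^2) * scale(resid_on(noise, u))[, 1] + scale(u)[, 1]
  comps <- list(cbind(scale(u)[, 1]), cbind(scale(w)[, 1]),
                cbind(scale(w)[, 1]))
  r_uw <- cor(u, w)
  expected <- mean(c(r_uw, r_uw, 1))
  expect_equal(canonical_correlations(comps), expected, tolerance = 1e-12)

  # sign case and identity case
  expect_equal(canonical_correlations(list(cbind(u), cbind(u))), 1)
  expect_equal(canonical_correlations(list(cbind(u), cbind(-u))), -1)

  # a three-set fit reports the mean over the 3 pairs
  blocks <- random_blocks(61, n = 80, ps = c(3, 3, 3))
  m <- fit_cca(blocks, reg = 0, n_components = 2)
  pair_mean <- sapply(1:2, function(k) {
    mean(c(cor(m$components[[1]][, k], m$components[[2]][, k]),
           cor(m$components[[1]][, k], m$components[[3]][, k]),
           cor(m$components[[2]][, k], m$components[[3]][, k])))
  })
  expect_equal(m$cancorrs, pair_mean, tolerance = 1e-12)
})

test_that("fit validation errors and warnings fire", {
  blocks <- random_blocks(70, n = 30, ps = c(3, 4))
  expect_error(fit_cca(blocks, n_components = 4), "smallest feature")
  expect_error(fit_cca(blocks[1]), "at least 2")
  expect_warning(
    fit_cca(blocks, reg = 0, n_components = 2, kernel = kernel_spec("linear")),
    "trivial")
  expect_error(
    fit_cca(list(matrix(rnorm(30), 10, 3), matrix(rnorm(33), 11, 3))),
    "mismatch")
  zero_var <- list(cbind(rep(0, 10)), cbind(rnorm(10)))
  expect_warning(canonical_correlations(zero_var), "zero-variance")
})
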