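# Successive projections algorithm: standardization, projection chains,
# PRESS evaluation, F-test pruning.

test_that("standardization uses the population convention", {
  X <- cbind(a = c(1, 2, 3), b = c(4, 0, 2))
  std <- spaStandardize(X)
  expect_equal(std$Z[, 1], c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(std$Z[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(colMeans(std$Z), c(a = 0, b = 0))
  expect_equal(sqrt(colMeans(std$Z^2)), c(a = 1, b = 1))
  expect_equal(std$convention, "population")
  # idempotence on already-standardized data
  expect_equal(spaStandardize(std$Z)$Z, std$Z)
  expect_error(spaStandardize(cbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance band\\(s\\): 1")
})

test_that("projection chain orders orthogonal columns by norm", {
  Z <- cbind(c(3, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 1, 0))
  expect_equal(projectionChain(Z, start = 1, kMax = 3), c(1L, 2L, 3L))
  # starting elsewhere: remaining columns still ranked by residual norm
  expect_equal(projectionChain(Z, start = 3, kMax = 3), c(3L, 1L, 2L))
})

test_that("exactly collinear columns are never chained", {
  withr::with_seed(8, Z <- matrix(rnorm(40), 10, 4))
  Zdup <- cbind(Z, 2 * Z[, 2])          # column 5 duplicates column 2
  ch <- projectionChain(Zdup, start = 2, kMax = 5)
  expect_false(5L %in% ch[1:2])
  expect_false(all(c(2L, 5L) %in% ch))  # duplicate excluded entirely
})

test_that("residual norms weakly decrease along a chain", {
  withr::with_seed(9, Z <- scale(matrix(rnorm(20 * 6), 20, 6)))
  ch <- projectionChain(Z, start = 1, kMax = 6)
  # oracle: explicit re-orthogonalization via QR at every prefix
  norms <- vapply(seq_along(ch)[-1], function(k) {
    Q <- qr.Q(qr(Z[, ch[1:(k - 1)], drop = FALSE]))
    resid <- Z[, ch[k]] - Q %*% crossprod(Q, Z[, ch[k]])
    sqrt(sum(resid^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("PRESS finds a noiseless informative subset", {
  withr::with_seed(10, {
    X <- matrix(rnorm(60 * 60), 60, 60)
    X[, c(10, 50)] <- X[, c(10, 50)] * 3   # informative bands carry variance
    y <- 2 * X[, 10] - X[, 50]
  })
  cal <- 1:40; val <- 41:60
  chains <- lapply(seq_len(60), function(s)
    projectionChain(X[cal, ], s, 6))
  res <- pressEvaluate(chains, X[cal, ], y[cal], X[val, ], y[val],
                       kMin = 2, kMax = 6)
  expect_true(all(c(10L, 50L) %in% selectedBands(res)))
  expect_lt(res@press, 1e-18)
  # single chain, single informative column
  y1 <- X[, 7] * 3
  res1 <- pressEvaluate(list(c(7L, 1L, 2L)), X[cal, ], y1[cal],
                        X[val, ], y1[val], kMin = 1, kMax = 1)
  expect_equal(selectedBands(res1), 7L)
})

test_that("winner matches brute force over all subsets on small instances", {
  # noiseless constructions with dominant-variance informative columns: the
  # global PRESS optimum (zero) is attainable by a chain prefix, so greedy
  # SPA and the exhaustive search must agree
  for (s in 1:4) {
    withr::with_seed(30 + s, {
      X <- matrix(rnorm(40 * 6), 40, 6)
      supp <- sort(sample(6, 2))
      X[, supp] <- X[, supp] * 3
      y <- X[, supp[1]] - 1.5 * X[, supp[2]]
    })
    cal <- 1:28; val <- 29:40
    chains <- lapply(1:6, function(st) projectionChain(X[cal, ], st, 6))
    res <- pressEvaluate(chains, X[cal, ], y[cal], X[val, ], y[val],
                         kMin = 2, kMax = 3)
    oracle <- bruteForcePress(X[cal, ], y[cal], X[val, ], y[val], 2, 3)
    expect_lt(abs(res@press - oracle$press), 1e-12)
    expect_true(all(supp %in% selectedBands(res)))
    expect_true(all(supp %in% oracle$vars))
  }
})

test_that("F-test pruning keeps informative variables and drops noise", {
  # all informative, non-redundant -> nothing pruned
  withr::with_seed(40, {
    X <- matrix(rnorm(80 * 5), 80, 5)
    y <- X %*% c(1, -1, 0.8, 1.2, -0.7) + rnorm(80, sd = 0.05)
  })
  res <- runSPA(X, as.numeric(y), kMin = 5, kMax = 5, seed = 2)
  expect_setequal(selectedBands(res), 1:5)
  # a winning subset padded with a pure-noise column: the noise column ranks
  # last by relevance and is pruned in >= 18/20 seeded repetitions
  pruned <- vapply(1:20, function(s) {
    withr::with_seed(50 + s, {
      X2 <- matrix(rnorm(80 * 4), 80, 4)
      y2 <- X2[, 1] + 0.8 * X2[, 2] + rnorm(80, sd = 0.05)
    })
    cal <- 1:56; val <- 57:80
    win <- pressEvaluate(list(1:4), X2[cal, ], y2[cal], X2[val, ],
                         y2[val], kMin = 4, kMax = 4)
    pr <- ftestPrune(win, X2[cal, ], y2[cal], X2[val, ], y2[val])
    !(4L %in% selectedBands(pr))
  }, logical(1))
  expect_gte(sum(pruned), 18L)
  # single-variable subsets pass through unchanged
  one <- new("SpaResult", selected = 3L, wavelengths = 600,
             pressBySize = c(`1` = 0.5), press = 0.5, relevance = 1,
             chainStart = 3L)
  withr::with_seed(60, {
    Xs <- matrix(rnorm(40 * 4), 40, 4); ys <- Xs[, 3] + rnorm(40, sd = 0.01)
  })
  kept <- ftestPrune(one, Xs[1:28, ], ys[1:28], Xs[29:40, ], ys[29:40])
  expect_equal(selectedBands(kept), 3L)
  expect_error(ftestPrune(one, Xs[1:38, ], ys[1:38], Xs[39:40, ],
                          ys[39:40]), "n < 3")
})

test_that("selected count never exceeds min(kMax, n_cal - 2)", {
  withr::with_seed(70, {
    X <- matrix(rnorm(14 * 30), 14, 30)
    y <- rnorm(14)
  })
  res <- runSPA(X, y, kMin = 1, kMax = 30, seed = 1)
  nCal <- 14 - max(3, round(0.3 * 14))
  expect_lte(length(selectedBands(res)), min(30, nCal - 2))
})

test_that("SPA results serialize to JSON", {
  withr::with_seed(80, {
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- X[, 2] - X[, 6] + rnorm(60, sd = 0.02)
  })
  res <- runSPA(X, y, kMin = 2, kMax = 4, seed = 1,
                grid = seq(400, 1000, length.out = 8))
  path <- file.path(withr::local_tempdir(), "spa.json")
  writeSpaResult(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sort(back$selected_indices), sort(selectedBands(res)))
  expect_equal(back$press, res@press)
})
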