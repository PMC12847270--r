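test_that("mean normalization gives unit column means", {
  expect_equal(normalize_by_mean(cbind(x = c(1, 2, 3))),
               cbind(x = c(0.5, 1, 1.5)))
  expect_equal(unname(normalize_by_mean(cbind(c(4, 4, 4)))),
               cbind(c(1, 1, 1)))
  withr::with_seed(21, {
    X <- matrix(runif(60, 0.1, 50), 5, 12)
    expect_equal(colMeans(normalize_by_mean(X)), rep(1, 12),
                 tolerance = 1e-12)
  })
})

test_that("min-max rescaling maps best to 0 and worst to 1", {
  expect_equal(rescale_minmax(c(0.5, 1.0, 1.5)), c(1, 0.5, 0))
  expect_equal(rescale_minmax(c(2, 7)), c(1, 0))
  expect_equal(rescale_minmax(c(0.5, 1.5), orientation = "cost"), c(0, 1))
  withr::with_seed(22, {
    y <- runif(9)
    w <- rescale_minmax(y)
    expect_equal(range(w), c(0, 1))
  })
  expect_error(rescale_minmax(c(1, 1, 1)), class = "psq_degenerate_error")
})

test_that("grey coefficients match hand-evaluated arithmetic", {
  # literal closed form, a = 0, rho = 0.5, column (0.5, 1.0, 1.5)
  expect_equal(grey_coefficient(c(0.5, 1.0, 1.5), rho = 0.5, a_ref = 0,
                                mode = "paper_literal"),
               c(1.25 / 1.25, 1.25 / 1.75, 1.25 / 2.25), tolerance = 1e-14)
  # Deng coefficient on deviations (0, 0.5, 1) with global extremes 0/1
  expect_equal(grey_coefficient(c(0, 0.5, 1), rho = 0.5,
                                mode = "deng_standard"),
               c(1, 0.5, 1 / 3), tolerance = 1e-14)
  # zero deviation always earns coefficient 1 in Deng mode
  withr::with_seed(23, {
    v <- c(0, runif(6))
    expect_equal(grey_coefficient(v, rho = runif(1, 0.05, 1),
                                  mode = "deng_standard")[1], 1)
  })
  expect_error(grey_coefficient(c(0, 0), mode = "deng_standard"),
               class = "psq_degenerate_error")
  expect_error(grey_coefficient(c(1, 2), rho = 0), class = "psq_validation_error")
})

test_that("grd is the row mean and ranking agrees with the sort oracle", {
  withr::with_seed(24, {
    eps <- matrix(runif(40), 5, 8, dimnames = list(paste0("T", 1:5), NULL))
    expect_equal(grd(eps), rowMeans(eps))
  })
  expect_equal(unname(grd(matrix(0.7, 3, 4))), rep(0.7, 3))
  # published degree column reproduces the published sort order
  beta <- c(RT = 0.861, IRT = 1.090, I70 = 0.991, IS = 1.267, IO = 1.391)
  rk <- rank_treatments(beta)
  expect_equal(rk$rank, c(5, 3, 4, 2, 1))
  expect_false(any(rk$tied))
  withr::with_seed(25, {
    for (i in 1:25) {
      b <- runif(6)
      expect_equal(rank_treatments(b)$rank, rank(-b, ties.method = "first"))
    }
  })
  tie <- rank_treatments(c(a = 1, b = 1, c = 0.5))
  expect_equal(tie$rank, c(1, 2, 3))
  expect_equal(tie$tied, c(TRUE, TRUE, FALSE))
})

test_that("deng_standard degrees live in (0, 1] with 1 iff fully dominant", {
  withr::with_seed(26, {
    for (i in 1:50) {
      X <- matrix(runif(5 * 7, 0.5, 20), 5, 7,
                  dimnames = list(paste0("T", 1:5), NULL))
      res <- gra(X, mode = "deng_standard")
      expect_true(all(res$coefficients > 0 & res$coefficients <= 1))
      expect_true(all(res$grd > 0 & res$grd <= 1))
      expect_setequal(res$ranking$rank, 1:5)
    }
  })
  # a treatment that is per-index best everywhere gets degree exactly 1
  X <- rbind(best = c(10, 5, 8), mid = c(9, 4, 7), low = c(8, 3, 6))
  expect_equal(unname(gra(X)$grd["best"]), 1)
})

test_that("GRA is invariant to rescaling any raw index column", {
  withr::with_seed(27, {
    X <- matrix(runif(50, 1, 30), 5, 10,
                dimnames = list(paste0("T", 1:5), paste0("I", 1:10)))
    for (mode in c("deng_standard", "paper_literal")) {
      base <- gra(X, mode = mode)
      Y <- X
      Y[, 4] <- Y[, 4] * 137.5
      Y[, 9] <- Y[, 9] * 0.004
      scaled <- gra(Y, mode = mode)
      expect_equal(scaled$grd, base$grd, tolerance = 1e-12)
      expect_equal(scaled$ranking$rank, base$ranking$rank)
    }
  })
})

test_that("dominance on every oriented index forces rank 1 (deng mode)", {
  withr::with_seed(28, {
    for (i in 1:50) {
      X <- matrix(runif(4 * 6, 1, 10), 4, 6,
                  dimnames = list(paste0("T", 1:4), NULL))
      winner <- sample(1:4, 1)
      X[winner, ] <- apply(X, 2, max) * runif(6, 1.001, 1.2)
      res <- gra(X, mode = "deng_standard")
      expect_equal(res$ranking$rank[winner], 1)
    }
  })
  # with a cost index, dominance means the smallest value there
  X <- rbind(T1 = c(10, 1), T2 = c(8, 2), T3 = c(6, 3))
  res <- gra(X, orientation = c("benefit", "cost"))
  expect_equal(res$ranking$rank[1], 1)
})

test_that("Deng coefficients increase with rho for non-reference entries", {
  withr::with_seed(29, {
    X <- matrix(runif(20, 1, 10), 4, 5, dimnames = list(paste0("T", 1:4), NULL))
    rhos <- seq(0.1, 1, by = 0.1)
    eps <- vapply(rhos, function(r) gra(X, rho = r)$coefficients,
                  matrix(0, 4, 5))
    nonref <- eps[, , 1] < 1
    for (k in seq_along(rhos)[-1]) {
      expect_true(all(eps[, , k][nonref] > eps[, , k - 1][nonref]))
    }
  })
})

test_that("grey_matrix rejects invalid inputs", {
  X <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(grey_matrix(X - 1), class = "psq_validation_error")
  expect_error(grey_matrix(X, rho = 0), class = "psq_validation_error")
  expect_error(grey_matrix(X[1, , drop = FALSE]), class = "psq_shape_error")
  expect_error(grey_matrix(unname(X)), class = "psq_shape_error")
})
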