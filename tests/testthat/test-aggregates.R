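test_that("fraction proportions, R0.25, MWD and GMD match hand values", {
  mass <- c(5, 5, 5, 15, 10, 10)
  expect_equal(fraction_proportions(mass), c(0.1, 0.1, 0.1, 0.3, 0.2, 0.2))
  expect_equal(r025(mass), 0.6)
  expect_equal(r025(c(0, 0, 0, 0, 0, 7)), 0)

  one_class <- c(0, 0, 50, 0, 0, 0)
  w <- fraction_proportions(one_class)
  expect_equal(w, c(0, 0, 1, 0, 0, 0))

  x <- default_diameters()
  expect_equal(mwd(c(0, 1, 0, 0, 0, 0), x), 1.5)
  expect_equal(mwd(c(0, 0.5, 0.5, 0, 0, 0), x), 1.125)
  # all mass in one class: both indices equal that class diameter
  expect_equal(mwd(w, x), 0.75)
  expect_equal(gmd(w, x), 0.75)
  # equal weights on synthetic diameters 1 and 4: geometric mean 2
  expect_equal(gmd(c(0.5, 0.5), c(1, 4)), 2)
  expect_equal(mwd(c(0.5, 0.5), c(1, 4)), 2.5)
})

test_that("degenerate and malformed inputs error", {
  expect_error(fraction_proportions(rep(0, 6)), class = "psq_degenerate_error")
  expect_error(fraction_proportions(c(-1, rep(1, 5))),
               class = "psq_validation_error")
  expect_error(mwd(c(0.5, 0.5), c(1, 2, 3)), class = "psq_shape_error")
  expect_error(gmd(c(0.5, 0.5), c(1, -1)), class = "psq_domain_error")
  # zero-weight classes may carry any diameter
  expect_equal(gmd(c(1, 0), c(2, -1)), 2)
})

test_that("indices agree with brute-force oracles on random samples", {
  x <- default_diameters()
  lower <- c(2, 1, 0.5, 0.25, 0.053, 0)
  withr::with_seed(11, {
    for (i in 1:200) {
      mass <- runif(6, 0, 30)
      w <- mass / sum(mass)
      expect_equal(fraction_proportions(mass), w)
      expect_equal(r025(mass), sum(mass[lower >= 0.25]) / sum(mass))
      expect_equal(mwd(w, x), sum(x * w))
      expect_equal(gmd(w, x), exp(sum(w * log(x)) / sum(w)))
    }
  })
})

test_that("aggregate index invariants hold over many random samples", {
  x <- default_diameters()
  withr::with_seed(12, {
    for (i in 1:1000) {
      mass <- runif(6, 0, 25)
      w <- fraction_proportions(mass)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      # weighted AM-GM: GMD <= MWD
      expect_lte(gmd(w, x), mwd(w, x) + 1e-12)
      # scale invariance of r025 and mwd
      s <- runif(1, 0.1, 10)
      expect_equal(r025(mass * s), r025(mass), tolerance = 1e-12)
      expect_equal(mwd(fraction_proportions(mass * s), x), mwd(w, x),
                   tolerance = 1e-12)
      # moving mass from a smaller to a larger class never decreases
      # mwd or r025
      from <- sample(2:6, 1)
      to <- sample(seq_len(from - 1), 1)
      shifted <- mass
      delta <- mass[from] * runif(1)
      shifted[from] <- shifted[from] - delta
      shifted[to] <- shifted[to] + delta
      expect_gte(r025(shifted) + 1e-12, r025(mass))
      expect_gte(mwd(fraction_proportions(shifted), x) + 1e-12, mwd(w, x))
    }
  })
  # equality GMD = MWD only when mass is concentrated in one class
  single <- c(0, 0, 0, 20, 0, 0)
  w1 <- fraction_proportions(single)
  expect_equal(gmd(w1, x), mwd(w1, x))
  spread <- fraction_proportions(c(5, 5, 5, 5, 5, 5))
  expect_lt(gmd(spread, x), mwd(spread, x))
})

test_that("aggregate_indices maps a sieve table row-wise", {
  sieve <- validate_table(make_sieve_df(), "sieve")
  out <- aggregate_indices(sieve)
  expect_equal(nrow(out), nrow(sieve))
  expect_equal(out$sample_id, sieve$sample_id)
  i <- 17
  mass <- as.numeric(sieve[i, schema_columns("sieve")[-(1:4)]])
  expect_equal(out$r025[i], r025(mass))
  expect_equal(out$mwd[i], mwd(fraction_proportions(mass)))
  expect_equal(rowSums(out[grep("^W_", names(out))]), rep(1, nrow(out)),
               ignore_attr = TRUE)
  pct <- aggregate_indices(sieve, as_percent = TRUE)
  expect_equal(rowSums(pct[grep("^W_", names(pct))]), rep(100, nrow(out)),
               ignore_attr = TRUE)
})
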