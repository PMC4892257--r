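test_that("shifted Hill satisfies its defining identities across parameters", {
  for (X0 in c(15, 200, 1e5)) {
    for (n in c(1, 2, 4, 6)) {
      for (lambda in c(0, 0.1, 1, 2, 10)) {
        sp <- hill_spec(X0, n, lambda)
        expect_equal(shifted_hill(X0, sp), (1 + lambda) / 2)
        expect_equal(shifted_hill(0, sp), 1)
        expect_equal(shifted_hill(1e6 * X0, sp), lambda, tolerance = 1e-3)
        # monotone: increasing for activation, decreasing for repression
        x <- seq(0, 5 * X0, length.out = 50)
        d <- diff(shifted_hill(x, sp))
        if (lambda > 1) expect_true(all(d > 0))
        if (lambda < 1) expect_true(all(d < 0))
        if (lambda == 1) expect_true(all(abs(d) < 1e-12))
      }
    }
  }
})

test_that("shifted Hill rejects invalid inputs", {
  sp <- hill_spec(100, 2, 0.5)
  expect_error(shifted_hill(-1, sp), "non-negative")
  expect_error(shifted_hill(NaN, sp), "finite")
  expect_error(hill_spec(-5, 2, 0.5))
  expect_error(hill_spec(100, 0, 0.5))
  expect_error(hill_spec(100, 2, -1))
})

test_that("microRNA repression matches the binomial-occupancy oracle", {
  rep6 <- mirna_spec(6, 10000, c(1, .6, .3, .1, .05, .05, .05),
                     c(0, .02, .1, .5, .5, .5, .5),
                     c(0, .0025, .025, .25, .25, .25, .25))
  mu <- seq(0, 1e5, length.out = 201)
  got <- mirna_repression(mu, rep6)
  # occupancy weights are Binomial(sites, x/(1+x)) probabilities
  x <- mu / rep6$mu0
  p_occ <- x / (1 + x)
  L <- sapply(p_occ, function(q) sum(rep6$translation * dbinom(0:6, 6, q)))
  Ym <- sapply(p_occ, function(q) sum(rep6$mrna_deg * dbinom(0:6, 6, q)))
  Yu <- sapply(p_occ, function(q) sum(0:6 * rep6$mirna_deg * dbinom(0:6, 6, q)))
  expect_equal(got$translation, L, tolerance = 1e-12)
  expect_equal(got$degradation, Ym, tolerance = 1e-12)
  expect_equal(got$mirna_loss, Yu, tolerance = 1e-12)
  # monotone translation, saturating limits
  expect_true(all(diff(got$translation) <= 1e-12))
  expect_equal(mirna_repression(0, rep6)$translation, 1)
  expect_equal(mirna_repression(0, rep6)$degradation, 0)
  sat <- mirna_repression(1e9 * rep6$mu0, rep6)
  expect_equal(sat$translation, 0.05, tolerance = 1e-6)
  expect_equal(sat$degradation, 0.5, tolerance = 1e-6)
  expect_equal(sat$mirna_loss, 6 * 0.25, tolerance = 1e-5)
})

test_that("microRNA record validation enforces its invariants", {
  expect_error(mirna_spec(2, 1e4, c(1, 0.6, 0.7)), "non-increasing")
  expect_error(mirna_spec(2, 1e4, c(1, 0.6)), "length")
  expect_error(mirna_spec(2, 1e4, c(1, .6, .3), mrna_deg = c(0, -1, 0)),
               "non-negative")
  expect_error(mirna_repression(-1, mirna_spec(2, 1e4, c(1, .6, .3))))
})
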