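test_that("maximum likelihood recovers Weibull shape and scale", {
  set.seed(101)
  x <- round(rweibull(10000, shape = 1.8, scale = 200))
  m <- fit_size_model(x)
  expect_lt(abs(m$delta - 1.8), 0.1)
  expect_lt(abs(m$eta - 200), 10)
})

test_that("truncated maximum likelihood recovers the pre-selection parameters", {
  set.seed(102)
  x <- rweibull(2e5, shape = 1, scale = 200)
  x <- x[x >= 150 & x <= 350][1:20000]
  m <- fit_size_model(x, truncation = c(150, 350))
  expect_lt(abs(m$delta - 1), 0.15)
  expect_lt(abs(m$eta - 200), 25)
})

test_that("degenerate or scarce input falls back to defaults with a warning", {
  expect_warning(m <- fit_size_model(rep(200L, 100L)), "defaults")
  expect_equal(m$eta, 200)
  expect_warning(m2 <- fit_size_model(c(180L, 220L)), "observations")
  expect_equal(m2$delta, 1.8)
})

test_that("fitted density integrates to one", {
  set.seed(103)
  m <- fit_size_model(round(rweibull(5000, 1.6, 220)))
  v <- stats::integrate(function(x) dweibull(x, m$delta, m$eta), 0, Inf)
  expect_lt(abs(v$value - 1), 1e-6)
  # the floored, half-base-corrected working density stays within 1e-3
  v2 <- stats::integrate(function(x) size_density(m, NA, x), 0, 5000,
                         subdivisions = 1000L)
  expect_lt(abs(v2$value - 1), 1e-3)
})

test_that("size_density matches closed forms, with floor and half-base correction", {
  m1 <- weibull_size_model(200, 1)
  expect_equal(size_density(m1, NA, 0), 1 / 200, tolerance = 1e-2)
  m2 <- weibull_size_model(200, 2)
  expect_equal(size_density(m2, NA, 200), (2 / 200) * exp(-1), tolerance = 1e-12)
  expect_equal(size_density(m2, NA, 1e9), m2$prob_floor)
  # zero-length gaps have finite, non-floored probability for any shape
  expect_gt(size_density(m2, NA, 0), m2$prob_floor)
})

test_that("copy likelihood is the geometric mean of fragment and gap probabilities", {
  m <- weibull_size_model(200, 1)
  cp <- transcript_copy("L", 1L, c("f1", "f2"), c(100L, 150L), c(10L, 20L, 30L))
  expected <- exp(mean(log(size_density(m, NA, c(100, 150, 10, 20, 30)))))
  expect_equal(copy_likelihood(cp, m, 1000), expected, tolerance = 1e-12)
  # direct arithmetic oracle against dweibull
  direct <- prod(dweibull(c(100, 150, 10, 20, 30), 1, 200))^(1 / 5)
  expect_equal(copy_likelihood(cp, m, 1000), direct, tolerance = 1e-6)
  # order-free: reversing the chain leaves L unchanged
  cp_rev <- transcript_copy("L", 1L, c("f2", "f1"), c(150L, 100L), c(30L, 20L, 10L))
  expect_equal(copy_likelihood(cp_rev, m, 1000), copy_likelihood(cp, m, 1000))
  expect_error(copy_likelihood(list(fragment_lengths = integer(0),
                                    gap_lengths = 0L), m, 1000), "no fragments")
})

test_that("effectiveness p-value matches numeric integration of the density region", {
  m <- weibull_size_model(200, 2)
  L <- dweibull(40, 2, 200)
  p <- effectiveness_pvalue(m, NA, L)
  # trapezoid integration over I(t) = {x : d(x) <= L}
  xs <- seq(0, 4000, by = 0.01)
  dx <- dweibull(xs, 2, 200)
  trap <- sum((dx * (dx <= L))[-1] + (dx * (dx <= L))[-length(xs)]) / 2 * 0.01
  expect_equal(p, trap, tolerance = 1e-3)
  # closed-form cross-check: p = F(x1) + 1 - F(x2)
  x2 <- uniroot(function(x) dweibull(x, 2, 200) - L, c(200, 4000))$root
  expect_equal(p, pweibull(40, 2, 200) + 1 - pweibull(x2, 2, 200),
               tolerance = 1e-8)
})

test_that("effectiveness p-value is monotone in L with the right limits", {
  m <- weibull_size_model(200, 1.8)
  mode <- 200 * ((1.8 - 1) / 1.8)^(1 / 1.8)
  dmax <- dweibull(mode, 1.8, 200)
  expect_equal(effectiveness_pvalue(m, NA, dmax), 1)
  expect_equal(effectiveness_pvalue(m, NA, 1), 1)
  Ls <- dmax * c(1e-6, 1e-3, 0.1, 0.5, 0.99)
  ps <- vapply(Ls, function(L) effectiveness_pvalue(m, NA, L), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(ps[1L], 1e-3)
  # monotone-density case (shape <= 1) uses the single upper crossing
  m1 <- weibull_size_model(200, 0.9)
  expect_equal(effectiveness_pvalue(m1, NA, 1), 1)
  expect_lt(effectiveness_pvalue(m1, NA, 1e-8), 0.1)
})

test_that("the ineffective rate is calibrated at tau for model-drawn copies", {
  # single-draw copies: p is uniform, so the rejection rate equals tau
  m <- weibull_size_model(200, 1.8)
  set.seed(104)
  x <- rweibull(20000, 1.8, 200)
  L <- dweibull(x, 1.8, 200)
  p <- vapply(L, function(l) effectiveness_pvalue(m, NA, l), numeric(1))
  rate <- mean(p <= 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(rate - 0.05), se3 + 1e-9)
})

test_that("classification direction satisfies the false-ineffective guarantee", {
  m <- weibull_size_model(200, 1.8)
  mode <- 200 * ((1.8 - 1) / 1.8)^(1 / 1.8)
  # copy at the mode: p = 1 -> effective for any tau < 1
  cp <- transcript_copy("L", 1L, "f1", round(mode), c(round(mode), round(mode)))
  expect_true(classify_effective(cp, m, NA, tau = 0.05))
  expect_false(classify_effective(cp, m, NA, tau = 0.05, paper_literal = TRUE))
  # one 20 bp fragment at the 5' end of a 10 kb isoform: huge terminal gap
  cp2 <- transcript_copy("L", 1L, "f1", 20L, c(0L, 9900L))
  expect_false(classify_effective(cp2, m, NA, tau = 0.05))
})

test_that("abundance formulas match hand-computed values and conserve totals", {
  # eTPM: eT = {3, 1} -> 750000 / 250000
  t1 <- compute_abundance(data.frame(isoform_id = c("A", "B"),
                                     length = c(1000, 1000),
                                     eT = c(3L, 1L), N = c(0, 0)))
  expect_equal(t1$eTPM, c(750000, 250000))
  # FPKM: N = 10, len 1000, total 10 -> 1e6
  t2 <- compute_abundance(data.frame(isoform_id = "A", length = 1000,
                                     eT = 0L, N = 10))
  expect_equal(t2$FPKM, 1e6)
  # TPM with len(r) = 250: N = {10,10}, len = {1000,2000}
  t3 <- compute_abundance(data.frame(isoform_id = c("A", "B"),
                                     length = c(1000, 2000),
                                     eT = c(1L, 1L), N = c(10, 10)),
                          expected_fragment_length = 250)
  expect_equal(t3$TPM, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(sum(t3$TPM), 1e6)
  expect_equal(sum(t3$eTPM), 1e6)
  # zero totals give all-zero columns; negative counts error
  t4 <- compute_abundance(data.frame(isoform_id = "A", length = 100,
                                     eT = 0L, N = 0))
  expect_equal(unlist(t4[, c("eTPM", "FPKM", "TPM")]), c(eTPM = 0, FPKM = 0, TPM = 0))
  expect_error(compute_abundance(data.frame(isoform_id = "A", length = 100,
                                            eT = -1L, N = 0)), "negative")
})

test_that("model parameters serialize and restore", {
  m <- weibull_size_model(123, 2.5, prob_floor = 1e-10)
  m2 <- size_model_from_params(size_model_params(m))
  expect_equal(m, m2)
})
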