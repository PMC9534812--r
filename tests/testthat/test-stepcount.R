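test_that("the binomial spot models are proper distributions", {
  x <- 0:10
  for (p_m in c(0.1, 0.47, 0.9)) for (A in c(0.5, 0.88, 1)) {
    expect_equal(sum(binomial_pmf(x, p_m = p_m, A = A)), 1,
                 tolerance = 1e-12)
    pr <- binomial_pmf(x, p_m = p_m, A = A, renormalize = TRUE)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_identical(pr[1], 0)
    for (H in c(0.3, 0.64)) for (het in 1:4) {
      expect_equal(sum(binomial_mixture_pmf(x, het = het, p_m = p_m,
                                            A = A, H = H)), 1,
                   tolerance = 1e-12)
      mr <- binomial_mixture_pmf(x, het = het, p_m = p_m, A = A, H = H,
                                 renormalize = TRUE)
      expect_equal(sum(mr), 1, tolerance = 1e-12)
      expect_identical(mr[1], 0)
    }
  }
})

test_that("the models reduce to their limiting cases", {
  x <- 0:10
  # single-complex spots only: a plain binomial of order 5
  expect_equal(binomial_pmf(x, p_m = 0.4, A = 1), dbinom(x, 5, 0.4))
  # all spots doubled: a plain binomial of order 10
  expect_equal(binomial_pmf(x, p_m = 0.4, A = 0), dbinom(x, 10, 0.4))
  # homomers only: the mixture collapses to the homo model
  expect_equal(binomial_mixture_pmf(x, het = 3, p_m = 0.47, A = 0.88, H = 1),
               binomial_pmf(x, p_m = 0.47, A = 0.88))
  # heteromer of full order: indistinguishable from the homo model
  expect_equal(binomial_mixture_pmf(x, het = 5, p_m = 0.47, A = 0.88,
                                    H = 0.3),
               binomial_pmf(x, p_m = 0.47, A = 0.88))
})

test_that("histograms aggregate accepted spots and drop weak fields", {
  steps <- c(1L, 2L, 2L, NA, 3L, 0L, 2L)
  h <- build_histogram(steps)
  expect_equal(unname(h$counts), c(1L, 3L, 1L))
  expect_identical(names(h$counts), c("1", "2", "3"))
  expect_identical(h$total, 5L)
  expect_identical(h$n_rejected, 2L)
  expect_length(h$fields_dropped, 0)
  # a field with < 10% accepted traces is dropped entirely
  field <- c(rep("a", 7), rep("b", 20))
  steps2 <- c(steps, c(2L, rep(NA, 19)))
  h2 <- build_histogram(steps2, field)
  expect_identical(h2$fields_dropped, "b")
  expect_identical(h2$total, 5L)
  # at exactly the threshold the field is kept
  steps3 <- c(steps, c(2L, 3L, rep(NA, 18)))
  h3 <- build_histogram(steps3, c(rep("a", 7), rep("b", 20)))
  expect_length(h3$fields_dropped, 0)
  expect_identical(h3$total, 7L)
  expect_warning(build_histogram(c(NA_integer_, 0L)), "empty")
})

test_that("the homo fit recovers exact expected-count histograms", {
  x <- 1:10
  counts <- setNames(1000 * binomial_pmf(x, p_m = 0.47, A = 0.88,
                                         renormalize = TRUE), x)
  fit <- fit_binomial(counts, "homo")
  expect_true(fit$converged)
  expect_equal(fit$p_m, 0.47, tolerance = 1e-3)
  expect_equal(fit$A, 0.88, tolerance = 1e-2)
  expect_lt(fit$chisq, 1e-3)
  expect_identical(fit$df, sum(counts > 0) - 3L)
  expect_gt(fit$p_value, 0.999)
})

test_that("the mixture fit recovers H from exact histograms", {
  x <- 1:10
  counts <- setNames(2000 * binomial_mixture_pmf(x, het = 3, p_m = 0.47,
                                                 A = 0.88, H = 0.64,
                                                 renormalize = TRUE), x)
  fit <- fit_binomial(counts, "mixture", het = 3, p_m = 0.47, A = 0.88)
  expect_identical(fit$free, "H")
  expect_equal(fit$H, 0.64, tolerance = 1e-3)
  expect_identical(fit$df, sum(counts > 0) - 2L)
})

test_that("fitting simulated spot counts recovers the truth statistically", {
  p <- bleach_sim_params(p_m = 0.47, A = 0.88)
  steps <- simulate_step_counts(p, 3000, seed = 11)
  fit <- fit_binomial(build_histogram(steps), "homo")
  expect_lt(abs(fit$p_m - 0.47), 0.05)
  expect_lt(abs(fit$A - 0.88), 0.07)
  expect_gt(fit$p_value, 0.01)
})

test_that("degenerate fits are rejected with clear errors", {
  expect_error(fit_binomial(setNames(integer(3), 1:3), "homo"), "empty")
  expect_error(fit_binomial(setNames(c(5L, 0L), 1:2), "homo"),
               "fewer than occupied")
})

test_that("scanning heteromer orders ranks the generating order first", {
  x <- 1:10
  counts <- setNames(round(5000 * binomial_mixture_pmf(
    x, het = 3, p_m = 0.47, A = 0.88, H = 0.3, renormalize = TRUE)), x)
  sc <- scan_heteromer_orders(counts, p_m = 0.47, A = 0.88)
  rk <- attr(sc, "ranking")
  expect_s3_class(rk, "data.frame")
  expect_setequal(rk$het, 1:4)
  expect_identical(rk$het[1], 3L)
  expect_true(all(diff(rk$p_value) <= 0))
  expect_equal(sc[[1]]$H, 0.3, tolerance = 0.05)
})

test_that("simulated het=3 data ranks het=3 first in most replicates", {
  # module-level model-selection property: pure heteromer population,
  # 300 observed spots per replicate, 100 replicates
  p <- bleach_sim_params(p_m = 0.47, A = 0.88, H = 0, het = 3L)
  wins <- 0L
  for (seed in 1:100) {
    steps <- simulate_step_counts(p, 300, seed = seed)
    h <- build_histogram(steps)
    sc <- scan_heteromer_orders(h, p_m = 0.47, A = 0.88, H = 0.1)
    if (attr(sc, "ranking")$het[1] == 3L) wins <- wins + 1L
  }
  expect_gte(wins, 80L)
})
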