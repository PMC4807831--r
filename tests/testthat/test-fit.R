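test_that("single-exponential fits recover the generative rate on noiseless data", {
  # tissular magnitude
  tac <- analytic_tac(halflife_to_lambda(2878))
  fit <- fit_single_exponential(tac)
  expect_true(fit$converged)
  expect_equal(fit$halflife, 2878, tolerance = 1e-3) # well inside 0.1%
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  # estimator consistency across lambda x duration in [0.5, 10]
  for (lt in c(0.5, 1, 2, 5, 10)) {
    lam <- lt / 3600
    f <- fit_single_exponential(analytic_tac(lam, A0 = 2e5))
    expect_equal(f$lambda, lam, tolerance = 1e-6)
  }

  # the optimizer lands on the generative parameters, not just near the
  # log-linear initialization
  lam <- halflife_to_lambda(500)
  f2 <- fit_single_exponential(analytic_tac(lam))
  expect_equal(f2$lambda, lam, tolerance = 1e-9)
  expect_equal(f2$residual_rms, 0, tolerance = 1e-10)
})

test_that("degenerate and windowed fits behave as documented", {
  # constant TAC: rate ~ 0, half-life reported infinite
  tac0 <- analytic_tac(0, A0 = 1000)
  f0 <- fit_single_exponential(tac0)
  expect_lt(f0$lambda, 1e-10)
  expect_identical(f0$halflife, Inf)

  # fit window restricts the frames used
  tac <- analytic_tac(halflife_to_lambda(600))
  fw <- fit_single_exponential(tac, window = c(600, Inf))
  expect_equal(fw$n_points, sum(tac$t_mid >= 600))
  expect_equal(fw$halflife, 600, tolerance = 1e-5)

  # fewer than 3 usable points is an error
  expect_error(fit_single_exponential(tac, window = c(3400, 3600)),
               "at least 3")

  # Poisson weighting on noiseless data changes nothing material
  fp <- fit_single_exponential(tac, weighting = "poisson")
  expect_equal(fp$halflife, 600, tolerance = 1e-5)

  # tidy/glance expose broom-style summaries
  td <- tidy(fw)
  expect_equal(td$term, c("amplitude", "lambda", "halflife"))
  gl <- glance(fw)
  expect_true(gl$converged)
  expect_equal(gl$t_min, 600)
})

test_that("alive/dead decomposition isolates the washout rate", {
  lam_t <- halflife_to_lambda(2878)
  lam_w <- halflife_to_lambda(330)
  fit_alive <- fit_single_exponential(analytic_tac(lam_t + lam_w))
  fit_dead <- fit_single_exponential(analytic_tac(lam_t))

  dec <- decompose_washout(fit_alive, fit_dead)
  expect_equal(dec$mode, "subtraction")
  # oracle: 1/(1/296.053616 - 1/2878) = 330 s
  expect_equal(dec$halflife_wash, 330, tolerance = 1e-6)
  expect_equal(dec$halflife_tiss, 2878, tolerance = 1e-6)
  expect_false(dec$no_washout)

  # identical rates: infinite washout half-life, flagged, no error
  same <- decompose_washout(fit_dead, fit_dead)
  expect_true(same$no_washout)
  expect_identical(same$halflife_wash, Inf)

  # direct mode returns the alive rate unchanged
  dd <- decompose_washout(fit_alive, fit_dead, mode = "direct")
  expect_equal(dd$lambda_wash, fit_alive$lambda)

  td <- tidy(dec)
  expect_equal(td$component, c("tissular", "alive_total", "washout"))
  expect_equal(td$halflife[3], 330, tolerance = 1e-6)
})

test_that("multi-exponential fit recovers fractions and reduces to one component", {
  proto <- acquisition_protocol(rep(100, 100))

  # three-component recovery: oracle = generation parameters
  m <- mizuno_params(c(0.5, 0.3, 0.2), c(0.01, 0.001, 0.0001))
  vals <- vapply(seq_len(nrow(proto)), function(f) {
    stats::integrate(function(t) eval_mizuno(m, t), proto$t_start[f],
                     proto$t_end[f], rel.tol = 1e-12)$value / proto$duration[f]
  }, numeric(1))
  tac3 <- as_tac(data.frame(t_start = proto$t_start,
                            duration = proto$duration, value = vals))
  fit3 <- fit_mizuno(tac3, 3)
  expect_true(fit3$converged)
  expect_equal(fit3$params$fractions, c(0.5, 0.3, 0.2), tolerance = 0.01)
  expect_equal(fit3$params$lambdas, c(0.01, 0.001, 0.0001), tolerance = 0.01)
  expect_equal(sum(fit3$params$fractions), 1, tolerance = 1e-9)

  # one component agrees with the single-exponential fit
  tac1 <- analytic_tac(halflife_to_lambda(900))
  f1 <- fit_mizuno(tac1, 1)
  fs <- fit_single_exponential(tac1)
  expect_equal(f1$params$lambdas[1], fs$lambda, tolerance = 1e-8)
  expect_equal(f1$A0, fs$amplitude, tolerance = 1e-6)

  # fractions sum to one even under noise
  set.seed(31)
  noisy <- tac3
  noisy$value <- noisy$value * exp(rnorm(nrow(noisy), 0, 0.02))
  fn <- fit_mizuno(noisy, 2)
  expect_equal(sum(fn$params$fractions), 1, tolerance = 1e-9)

  expect_error(fit_mizuno(analytic_tac(1e-3,
                                       protocol = acquisition_protocol(rep(30, 5))), 3),
               "at least 7")
})

test_that("components with collapsed rates are merged and flagged", {
  # generative curve is a single exponential; a 2-component fit cannot
  # separate it
  tac <- analytic_tac(halflife_to_lambda(600),
                      protocol = acquisition_protocol(rep(60, 30)))
  fit <- fit_mizuno(tac, 2)
  # either the rates collapsed and were merged, or one fraction is ~ 0
  expect_true(fit$collapsed || min(fit$params$fractions[1:2]) < 1e-3 ||
                fit$lambda_gap < 0.5)
  expect_equal(sum(fit$params$fractions), 1, tolerance = 1e-9)
})

test_that("group summaries report mean and sample SD of half-lives", {
  g <- summarize_group(c(330, 330, 330, 330), "brain", "washout")
  expect_equal(g$mean_halflife, 330)
  expect_equal(g$sd_halflife, 0)
  expect_equal(g$n, 4L)

  # oracle: two-point sample SD = |360-300|/sqrt(2) = 42.4264
  g2 <- summarize_group(c(300, 360), "brain", "washout")
  expect_equal(g2$mean_halflife, 330)
  expect_equal(g2$sd_halflife, 42.42640687, tolerance = 1e-8)

  g1 <- summarize_group(621, "tumor", "washout")
  expect_equal(g1$n, 1L)
  expect_equal(g1$sd_halflife, 0)

  gd <- summarize_group(data.frame(halflife = c(300, 360)), "brain", "washout")
  expect_equal(gd$mean_halflife, 330)

  expect_error(summarize_group(numeric(0), "brain", "washout"), "no half-lives")
})
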