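## make a survival_dataset from raw vectors plus optional covariates
as_sd <- function(time, event, ...) {
  df <- data.frame(time = time, event = event, ...)
  cov <- setdiff(names(df), c("time", "event"))
  survival_dataset(df, latency = cov, incidence = cov)
}

test_that("cure log-likelihood matches a term-by-term hand evaluation", {
  ## three subjects, pi = 0.5 (intercept-only, b0 = 0), Weibull with
  ## rho = 2 and unit rate: S_u(t) = exp(-t^2), f_u(t) = 2 t exp(-t^2);
  ## AFT equivalent mu = 0, sigma = 0.5
  d <- as_sd(c(1, 2, 3), c(1, 0, 1))
  spec <- cure_spec()
  ll <- cure_loglik(c(0, 0, 0.5), d, spec)
  hand <- log(0.5 * 2 * exp(-1)) +
    log(1 - 0.5 + 0.5 * exp(-4)) +
    log(0.5 * 6 * exp(-9))
  expect_equal(ll, hand, tolerance = 1e-12)
})

test_that("a certainly-cured censored subject contributes zero", {
  d <- as_sd(5, 0)
  ## pi = 0 exactly in the -Inf odds limit: contribution log(1) = 0
  expect_identical(cure_loglik(c(-Inf, 0, 1), d, cure_spec()), 0)
  ## at the clip boundary pi is numerically zero
  ll <- cure_loglik(c(-30, 0, 1), d, cure_spec())
  expect_lt(abs(ll), 1e-10)
})

test_that("with pi pinned at one the likelihood is censored-Weibull", {
  set.seed(21)
  for (rep in 1:5) {
    dat <- make_weibull_data(200)
    d <- as_sd(dat$time, dat$event, x = dat$x)
    spec <- cure_spec(latency = "x")
    mu <- rnorm(1); g <- rnorm(1); sg <- runif(1, 0.3, 2)
    ll <- cure_loglik(c(Inf, mu, g, sg), d, spec)
    expect_equal(ll, oracle_weibull_loglik(dat$time, dat$event,
                                           mu + g * dat$x, sg),
                 tolerance = 1e-8)
  }
})

test_that("invalid inputs to the likelihood are rejected", {
  d <- as_sd(c(1, 2), c(1, 0))
  expect_error(cure_loglik(c(0, 0, -1), d, cure_spec()), "sigma")
  expect_error(cure_loglik(c(0, 0), d, cure_spec()), "expected 3")
  d0 <- as_sd(c(0, 2), c(1, 0))
  expect_error(cure_loglik(c(0, 0, 1), d0, cure_spec()),
               "strictly positive")
})

test_that("fitting recovers the generating parameters at n = 2000", {
  set.seed(22)
  truth <- generative_params(b0 = 0.85, b1 = 1, b2 = -1, c0 = 0, c1 = 1,
                             rho = 2)
  d <- simulate_dataset(truth, 2000, censor_rate_param = 0.25)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  expect_true(fit$converged)
  ## AFT truth: mu = -c0*sigma = 0, gamma = -c1*sigma = -0.5, sigma = 0.5
  true_par <- c(0.85, 1, -1, 0, -0.5, 0.5)
  expect_true(all(abs(fit$coefficients - true_par) < 3 * fit$se))
})

test_that("all-events data reduce to the plain Weibull fit", {
  set.seed(23)
  dat <- make_weibull_data(400, censor_rate = 0)
  d <- as_sd(dat$time, dat$event, x = dat$x)
  fit <- fit_pmcm(d, cure_spec(latency = "x"))
  sr <- survival::survreg(survival::Surv(dat$time, dat$event) ~ dat$x,
                          dist = "weibull")
  expect_equal(unname(fit$coefficients[c("lat:(Intercept)", "lat:x")]),
               unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$sigma, sr$scale, tolerance = 1e-4)
  ## estimated susceptible probability at the boundary
  expect_gt(plogis(fit$b[[1]]), 0.999)
})

test_that("the AIC identity holds for every fit", {
  set.seed(24)
  d <- simulate_dataset(generative_params(b0 = 1), 300,
                        censor_rate_param = 0.3)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  expect_equal(fit$k, 6)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(dim(fit$vcov), c(fit$k, fit$k))
  fit2 <- fit_pmcm(d, cure_spec(incidence = "z1"))
  expect_equal(fit2$k, 4)
  expect_equal(fit2$aic, 8 - 2 * fit2$loglik)
})

test_that("marginal survival is a proper survival curve with a plateau", {
  set.seed(25)
  d <- simulate_dataset(generative_params(b0 = 0.5), 400,
                        censor_rate_param = 0.3)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  z <- c(0.3, 0.6); x <- 0.4
  tt <- c(0, 10^seq(-3, 2, length.out = 40))
  s <- predict_marginal_survival(fit, tt, x = x, z = z)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
  pi <- plogis(sum(fit$b * c(1, z)))
  expect_equal(predict_marginal_survival(fit, 1e9, x = x, z = z),
               1 - pi, tolerance = 1e-6)
  expect_error(predict_marginal_survival(fit, -1, x = x, z = z),
               "nonnegative")
})

test_that("median survival: closed form, undefined case, root roundtrip", {
  set.seed(26)
  d <- simulate_dataset(generative_params(b0 = 1.5), 500,
                        censor_rate_param = 0.25)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  ## uncured closed form against direct evaluation
  mu <- fit$mu; g <- fit$gamma[[1]]; sg <- fit$sigma
  expect_equal(median_survival_time(fit, x = 0.5, population = "uncured"),
               exp(mu + 0.5 * g) * log(2)^sg)
  ## marginal median solves S = 1/2 when defined
  z <- c(1, 0.5)
  m <- median_survival_time(fit, x = 0.5, z = z, population = "marginal")
  if (!is.na(m))
    expect_equal(predict_marginal_survival(fit, m, x = 0.5, z = z), 0.5,
                 tolerance = 1e-6)
  ## cured plateau above one half: undefined
  fit2 <- fit
  fit2$b <- c(`(Intercept)` = qlogis(0.4))
  fit2$spec <- cure_spec(latency = "x")
  expect_true(is.na(median_survival_time(fit2, x = 0.5,
                                         population = "marginal")))
})

test_that("unit-exponential uncured median is log 2", {
  fit <- structure(list(b = c(`(Intercept)` = 0), mu = 0,
                        gamma = numeric(0), sigma = 1,
                        spec = cure_spec()),
                   class = "pmcm_fit")
  expect_equal(median_survival_time(fit, population = "uncured"), log(2))
})

test_that("estimated cure fraction: logistic-at-zero and recovery", {
  set.seed(27)
  d <- simulate_dataset(generative_params(b0 = 0.5), 400,
                        censor_rate_param = 0.3)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  fit0 <- fit
  fit0$b <- c(`(Intercept)` = 0)
  fit0$spec <- cure_spec(latency = "x")
  expect_equal(estimated_cure_fraction(fit0, d), 0.5)
  fit1 <- fit0
  fit1$b <- c(`(Intercept)` = 40)
  expect_equal(estimated_cure_fraction(fit1, d), 0, tolerance = 1e-12)
})

test_that("cure-fraction estimate recovers a 30% generating rate", {
  set.seed(28)
  cal <- calibrate_intercepts(generative_params(), target_cure = 0.30,
                              target_censor = 0.40)
  d <- simulate_dataset(cal$params, 5000, cal$censor_rate_param)
  fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
  expect_lt(abs(estimated_cure_fraction(fit, d) - 0.30), 0.03)
})

test_that("backward selection drops a noise covariate, keeps signal", {
  set.seed(29)
  cal <- calibrate_intercepts(generative_params(), 0.25, 0.35)
  d <- simulate_dataset(cal$params, 2000, cal$censor_rate_param)
  d$data$junk <- rnorm(2000)
  spec <- cure_spec(incidence = c("z1", "z2"), latency = c("x", "junk"))
  sel <- backward_select(d, spec, alpha = 0.05)
  expect_false("junk" %in% sel$latency)
  expect_true("x" %in% sel$latency)
  expect_true(all(c("z1", "z2") %in% sel$incidence))
  fit <- attr(sel, "fit")
  ## selection is a no-op when everything remaining is significant
  sel2 <- backward_select(d, sel, alpha = 0.05)
  expect_identical(unclass(sel2)[c("incidence", "latency")],
                   unclass(sel)[c("incidence", "latency")])
})
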