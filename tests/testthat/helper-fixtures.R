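## Shared fixture builders for the test suite.  Everything is generated
## in code under explicit seeds; no data files.

## censored Weibull sample with one covariate, AFT truth
make_weibull_data <- function(n, mu = 0, gamma = 0.8, sigma = 0.5,
                              censor_rate = 0.3) {
  x <- runif(n)
  W <- log(-log(runif(n)))
  t <- exp(mu + gamma * x + sigma * W)
  cc <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  list(time = pmin(t, cc), event = as.integer(t <= cc), x = x,
       X = cbind(`(Intercept)` = rep(1, n), x = x))
}

## independent censored-Weibull log-likelihood via stats d/p functions
## (time-scale), used as the oracle against the package's own code
oracle_weibull_loglik <- function(time, event, eta, sigma) {
  shape <- 1 / sigma
  scale <- exp(eta)
  sum(ifelse(event == 1,
             stats::dweibull(time, shape, scale, log = TRUE),
             stats::pweibull(time, shape, scale, lower.tail = FALSE,
                             log.p = TRUE)))
}

## two-regime (single-threshold) dataset for tree tests: mu jumps by
## `jump` where the partitioning variable u exceeds `threshold`
make_two_regime_data <- function(n, jump = 2, threshold = 0.5,
                                 sigma = 0.5, censor_rate = 0.1,
                                 extra_noise_vars = 0) {
  u <- runif(n)
  mu <- ifelse(u <= threshold, 0, jump)
  W <- log(-log(runif(n)))
  t <- exp(mu + sigma * W)
  cc <- rexp(n, censor_rate)
  df <- data.frame(time = pmin(t, cc), event = as.integer(t <= cc), u = u)
  part <- "u"
  if (extra_noise_vars > 0) {
    for (j in seq_len(extra_noise_vars)) {
      nm <- paste0("noise", j)
      df[[nm]] <- rnorm(n)
      part <- c(part, nm)
    }
  }
  survival_dataset(df, time = "time", event = "event",
                   latency = character(), partitioning = part)
}

## homogeneous Weibull dataset with pure-noise partitioning variables
make_homogeneous_data <- function(n, n_noise = 3, sigma = 1,
                                  censor_rate = 0.3) {
  W <- log(-log(runif(n)))
  t <- exp(sigma * W)
  cc <- rexp(n, censor_rate)
  df <- data.frame(time = pmin(t, cc), event = as.integer(t <= cc))
  part <- character(0)
  for (j in seq_len(n_noise)) {
    nm <- paste0("noise", j)
    df[[nm]] <- rnorm(n)
    part <- c(part, nm)
  }
  survival_dataset(df, time = "time", event = "event",
                   latency = character(), partitioning = part)
}
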