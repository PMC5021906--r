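## Logistic-Weibull parametric mixture cure model (PMCM).
##
## Marginal survival: S(t | x, z) = pi(z) S_u(t | x) + 1 - pi(z), where
## pi(z) = plogis(b' z) is the incidence (probability of being susceptible)
## and S_u is the Weibull survival of the susceptible, in AFT form
## log T = mu + gamma' x + sigma W.  The proportional-hazards form
## S_u = exp(-exp(c0 + c1 x) t^rho) maps onto this via rho = 1/sigma,
## c0 = -mu/sigma, c_j = -gamma_j/sigma.

#' Specify the two parts of a mixture cure model
#'
#' @param incidence character vector of covariate columns for the logistic
#'   incidence part pi(z); may be empty (intercept-only).
#' @param latency character vector of covariate columns for the Weibull
#'   latency part; may be empty (intercept-only).
#' @return An object of class `"cure_spec"`.
#' @export
cure_spec <- function(incidence = character(), latency = character()) {
  structure(list(incidence = as.character(incidence),
                 latency = as.character(latency)),
            class = "cure_spec")
}

#' @export
print.cure_spec <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "1"
  cat("Cure model specification\n")
  cat("  incidence: ~", fmt(x$incidence), "\n")
  cat("  latency:   ~", fmt(x$latency), "\n")
  invisible(x)
}

## linear-predictor clip for the incidence part: beyond +-30 the logistic
## is numerically 0/1 and the likelihood is flat
PI_CLIP <- 30

cure_design <- function(data, spec) {
  validate_survival_dataset(data, require_event = FALSE)
  miss <- setdiff(c(spec$incidence, spec$latency), names(data$data))
  if (length(miss))
    stop("cure_spec names column(s) not in the data: ",
         paste(miss, collapse = ", "))
  list(Z = model_matrix_roles(data, spec$incidence, "incidence"),
       X = model_matrix_roles(data, spec$latency, "latency"),
       time = data$data[[data$time]],
       event = data$data[[data$event]])
}

## core likelihood pieces on the working scale (b, betalat, theta = log sigma)
cure_ll_work <- function(par, Z, X, logt, event) {
  q <- ncol(Z); p <- ncol(X)
  b <- par[seq_len(q)]
  beta <- par[q + seq_len(p)]
  theta <- par[q + p + 1L]
  sigma <- exp(theta)
  lp <- drop(Z %*% b)
  ## clip finite linear predictors; infinite ones encode exact pi = 0/1
  fin <- is.finite(lp)
  lp[fin] <- pmin(pmax(lp[fin], -PI_CLIP), PI_CLIP)
  pi <- stats::plogis(lp)
  w <- (logt - drop(X %*% beta)) / sigma
  ew <- exp(w)
  S <- exp(-ew)
  cdf <- -expm1(-ew)                       # 1 - S, accurate near 0
  ll_ev <- log(pi) + (-theta - logt + w - ew)
  ## log(1 - pi + pi S); at pi = 1 exactly this is log S = -exp(w)
  ll_ce <- ifelse(pi == 1, -ew, log1p(-pi * cdf))
  ll <- sum(ifelse(event == 1, ll_ev, ll_ce))
  list(ll = ll, pi = pi, w = w, ew = ew, S = S, cdf = cdf, sigma = sigma,
       theta = theta, q = q, p = p)
}

cure_grad_work <- function(parts, Z, X, event) {
  pi <- parts$pi; w <- parts$w; ew <- parts$ew; S <- parts$S
  sigma <- parts$sigma
  D <- pmax(1 - pi * parts$cdf, .Machine$double.xmin)
  ev <- event == 1
  dlp <- ifelse(ev, 1 - pi, pi * (1 - pi) * (S - 1) / D)
  deta <- ifelse(ev, (ew - 1) / sigma, pi * ew * S / (sigma * D))
  dtheta <- ifelse(ev, (ew - 1) * w - 1, pi * ew * S * w / D)
  c(crossprod(Z, dlp), crossprod(X, deta), sum(dtheta))
}

#' Observed-data log-likelihood of the Logistic-Weibull cure model
#'
#' Each subject with an observed event contributes
#' `log[pi(z) f_u(t | x)]`; each censored subject contributes
#' `log[1 - pi(z) + pi(z) S_u(t | x)]`.
#'
#' @param params natural-scale parameter vector
#'   `c(b, mu, gamma, sigma)`: incidence coefficients (intercept first),
#'   latency intercept and coefficients on the log-time scale, and the
#'   Weibull scale `sigma > 0` last.  Incidence coefficients may be
#'   `+-Inf`, encoding the exact degenerate limits `pi = 1` (everyone
#'   susceptible: the censored-Weibull log-likelihood) and `pi = 0`
#'   (everyone cured).  Finite incidence linear predictors are clipped at
#'   `+-30` before the logistic transform.
#' @param data a [survival_dataset()]; event times must be strictly
#'   positive (the Weibull density is evaluated at them).
#' @param spec a [cure_spec()].
#' @return The log-likelihood (a single number).
#' @export
cure_loglik <- function(params, data, spec) {
  des <- cure_design(data, spec)
  k <- ncol(des$Z) + ncol(des$X) + 1L
  if (length(params) != k)
    stop("expected ", k, " parameters, got ", length(params))
  q <- ncol(des$Z)
  ## incidence coefficients may be +-Inf (degenerate pi = 0/1 limits);
  ## latency parameters must be finite
  if (any(is.na(params)) || !all(is.finite(params[(q + 1):length(params)])))
    stop("non-finite parameter value")
  sigma <- params[length(params)]
  if (sigma <= 0) stop("sigma must be positive")
  if (any(des$time[des$event == 1] <= 0))
    stop("event times must be strictly positive")
  par_work <- c(params[-length(params)], log(sigma))
  cure_ll_work(par_work, des$Z, des$X,
               log(pmax(des$time, .Machine$double.xmin)), des$event)$ll
}

numeric_hessian_grad <- function(grad_fn, par, h_rel = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * (1 + abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

safe_solve_spd <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out))) return(list(V = out, ok = TRUE))
  ## pseudo-inverse via eigen decomposition, small eigenvalues dropped
  ee <- eigen(A, symmetric = TRUE)
  tol <- max(abs(ee$values)) * 1e-10
  inv <- ifelse(abs(ee$values) > tol, 1 / ee$values, 0)
  list(V = ee$vectors %*% (inv * t(ee$vectors)), ok = FALSE)
}

#' Fit the Logistic-Weibull parametric mixture cure model
#'
#' Direct maximum likelihood by quasi-Newton (BFGS) ascent of the
#' observed-data log-likelihood with analytic gradient, on the working
#' scale `(b, mu, gamma, log sigma)`.  Several starting points are tried
#' (a null-model start built from a Kaplan-Meier plateau estimate of the
#' cured fraction plus seeded perturbations) and the best local optimum is
#' kept.  Standard errors come from a central-difference Hessian of the
#' analytic gradient at the optimum.
#'
#' @param data a [survival_dataset()].
#' @param spec a [cure_spec()] naming the incidence and latency covariates.
#' @param init optional natural-scale start `c(b, mu, gamma, sigma)`.
#' @param seed integer seed for the perturbed restarts (default 1).
#' @param n_starts number of starting points (default 3; the first is the
#'   deterministic null-model start).
#' @param maxit iteration cap per start.
#'
#' @return An object of class `"pmcm_fit"` with elements `b`, `mu`,
#'   `gamma`, `sigma`, `coefficients` (all natural-scale parameters),
#'   `se`, `vcov`, `loglik`, `aic`, `k`, `n`, `n_events`, `converged`,
#'   `boundary` (incidence linear predictor pinned at the clip, i.e. a
#'   pi -> 0/1 boundary solution) and the `spec`.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(generative_params(b0 = 1, b1 = 1, b2 = -1,
#'                                         c0 = 0, c1 = 1, rho = 2),
#'                       n = 400, censor_rate_param = 0.2)
#' fit <- fit_pmcm(d, cure_spec(incidence = c("z1", "z2"), latency = "x"))
#' fit$aic
#' @export
fit_pmcm <- function(data, spec, init = NULL, seed = 1L,
                     n_starts = 3L, maxit = 500L) {
  des <- cure_design(data, spec)
  if (!any(des$event == 1))
    stop("at least one observed event is required to fit the model")
  if (any(des$time[des$event == 1] <= 0))
    stop("event times must be strictly positive")
  Z <- des$Z; X <- des$X
  q <- ncol(Z); p <- ncol(X)
  logt <- log(pmax(des$time, .Machine$double.xmin))
  event <- des$event
  k <- q + p + 1L

  nll <- function(par) -cure_ll_work(par, Z, X, logt, event)$ll
  ngr <- function(par) -cure_grad_work(cure_ll_work(par, Z, X, logt, event),
                                       Z, X, event)

  starts <- list()
  if (!is.null(init)) {
    stopifnot(length(init) == k, init[k] > 0)
    starts[[1]] <- c(init[-k], log(init[k]))
  } else {
    ## null start: latency from an all-susceptible Weibull fit, incidence
    ## intercept from the Kaplan-Meier plateau (1 - plateau susceptible)
    wf <- weibull_aft_fit(des$time, event, X)
    km <- kaplan_meier(des$time, event)
    plateau <- km_plateau_cure_estimate(km)
    b0 <- stats::qlogis(min(max(1 - plateau, 0.02), 0.98))
    starts[[1]] <- c(b0, rep(0, q - 1L), wf$beta, wf$theta)
  }
  if (n_starts > 1L) {
    base <- starts[[1]]
    pert <- with_preserved_seed(as.integer(seed), {
      lapply(seq_len(n_starts - 1L), function(i)
        base + stats::rnorm(k, sd = 0.5))
    })
    starts <- c(starts, pert)
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, nll, ngr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed")
  ## optim reports maxit-exhaustion on boundary ridges (pi -> 0/1) where
  ## the likelihood is flat; a small gradient there is still an optimum
  gnorm <- sqrt(sum(ngr(best$par)^2))
  converged <- best$convergence == 0 || gnorm < 1e-3 * (1 + abs(best$value))
  if (!converged)
    warning("PMCM optimization did not converge; returning best iterate")

  par <- unname(best$par)
  ll <- -best$value
  H <- numeric_hessian_grad(function(z) -ngr(z), par)
  vs <- safe_solve_spd(-H)
  if (!vs$ok)
    warning("Hessian near-singular at the optimum; ",
            "using a pseudo-inverse for the covariance")
  Vw <- vs$V
  sigma <- exp(par[k])
  ## delta transform log(sigma) -> sigma
  J <- diag(k); J[k, k] <- sigma
  V <- J %*% Vw %*% t(J)
  coefs <- c(par[seq_len(q + p)], sigma)
  nm <- c(paste0("inc:", colnames(Z)), paste0("lat:", colnames(X)), "sigma")
  names(coefs) <- nm
  dimnames(V) <- list(nm, nm)
  se <- sqrt(pmax(diag(V), 0))
  lp <- drop(Z %*% par[seq_len(q)])
  boundary <- any(abs(lp) >= PI_CLIP - 1e-6)

  structure(list(
    b = stats::setNames(par[seq_len(q)], colnames(Z)),
    mu = par[q + 1L],
    gamma = if (p > 1L) stats::setNames(par[q + 1L + seq_len(p - 1L)],
                                        colnames(X)[-1L]) else numeric(0),
    sigma = sigma,
    coefficients = coefs, se = se, vcov = V,
    loglik = ll, k = k, aic = 2 * k - 2 * ll,
    n = length(event), n_events = sum(event == 1),
    converged = converged, boundary = boundary,
    spec = spec, time_col = data$time, event_col = data$event
  ), class = "pmcm_fit")
}

#' @export
print.pmcm_fit <- function(x, ...) {
  cat("Logistic-Weibull mixture cure model\n")
  cat(sprintf("  n = %d, events = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$n_events, x$loglik, x$aic))
  if (!x$converged) cat("  (optimization did not converge)\n")
  if (x$boundary) cat("  (incidence boundary solution: pi ~ 0 or 1)\n")
  print(summary(x)$table, digits = 4)
  invisible(x)
}

#' Summarize a mixture cure model fit
#'
#' @param object a `"pmcm_fit"`.
#' @param level confidence level for the Wald intervals (default 0.95).
#' @param ... unused.
#' @return A list with a coefficient `table` (estimate, SE, Wald CI,
#'   p-value per term), `loglik` and `aic`.
#' @export
summary.pmcm_fit <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  se <- object$se
  zval <- est / se
  pv <- 2 * stats::pnorm(-abs(zval))
  ## sigma: positivity constraint, no null at zero to test
  pv[length(pv)] <- NA_real_
  tab <- data.frame(estimate = est, se = se,
                    lower = est - zq * se, upper = est + zq * se,
                    p_value = pv)
  out <- list(table = tab, loglik = object$loglik, aic = object$aic,
              level = level)
  class(out) <- "summary.pmcm_fit"
  out
}

#' @export
print.summary.pmcm_fit <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("logLik = %.3f   AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

pi_of_z <- function(fit, z) {
  zz <- c(1, as.numeric(z))
  if (length(zz) != length(fit$b))
    stop("expected ", length(fit$b) - 1L, " incidence covariate value(s)")
  unname(stats::plogis(min(max(sum(fit$b * zz), -PI_CLIP), PI_CLIP)))
}

latency_eta <- function(fit, x) {
  xx <- as.numeric(x)
  if (length(xx) != length(fit$gamma))
    stop("expected ", length(fit$gamma), " latency covariate value(s)")
  unname(fit$mu + if (length(xx)) sum(fit$gamma * xx) else 0)
}

#' Marginal survival probability from a fitted cure model
#'
#' Evaluates `S(t | x, z) = pi(z) S_u(t | x) + 1 - pi(z)`: the population
#' survival mixing the susceptible Weibull survival with the cured
#' plateau `1 - pi(z)`.
#'
#' @param fit a `"pmcm_fit"`.
#' @param t nonnegative time(s).
#' @param x latency covariate values, in the order of the fitted spec
#'   (omit when the latency part is intercept-only).
#' @param z incidence covariate values, likewise.
#' @return Survival probabilities in `[0, 1]`, nonincreasing in `t`, with
#'   `S(0) = 1` and limit `1 - pi(z)` as `t` grows.
#' @export
predict_marginal_survival <- function(fit, t, x = numeric(0), z = numeric(0)) {
  stopifnot(inherits(fit, "pmcm_fit"))
  if (any(t < 0)) stop("t must be nonnegative")
  pi <- pi_of_z(fit, z)
  eta <- latency_eta(fit, x)
  Su <- exp(-exp((log(t) - eta) / fit$sigma))
  Su[t == 0] <- 1
  pi * Su + 1 - pi
}

#' Median survival time under a fitted cure model
#'
#' For the uncured (susceptible) population the Weibull median is closed
#' form, `exp(mu + gamma' x) (log 2)^sigma`.  For the marginal population
#' the median solves `S(t | x, z) = 1/2` by bracketed root finding; it is
#' undefined (returned as `NA`) when the cured plateau `1 - pi(z)` is at
#' or above one half, because the marginal survival never crosses it.
#'
#' @inheritParams predict_marginal_survival
#' @param population `"uncured"` or `"marginal"`.
#' @param tol relative tolerance of the root finder.
#' @return A single time, or `NA` when the marginal median is undefined.
#' @export
median_survival_time <- function(fit, x = numeric(0), z = numeric(0),
                                 population = c("uncured", "marginal"),
                                 tol = 1e-10) {
  stopifnot(inherits(fit, "pmcm_fit"))
  population <- match.arg(population)
  eta <- latency_eta(fit, x)
  med_u <- exp(eta) * log(2)^fit$sigma
  if (population == "uncured") return(med_u)
  pi <- pi_of_z(fit, z)
  if (1 - pi >= 0.5) return(NA_real_)
  f <- function(t) predict_marginal_survival(fit, t, x, z) - 0.5
  upper <- med_u
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = tol * max(upper, 1))$root
}

#' Estimated cure fraction of a population
#'
#' Averages the fitted probability of being cured, `1 - pi(z_i)`, over the
#' subjects of a dataset.
#'
#' @param fit a `"pmcm_fit"`.
#' @param data a [survival_dataset()] carrying the incidence covariates.
#' @return A proportion in `[0, 1]`.
#' @export
estimated_cure_fraction <- function(fit, data) {
  stopifnot(inherits(fit, "pmcm_fit"))
  Z <- model_matrix_roles(data, fit$spec$incidence, "incidence")
  lp <- pmin(pmax(drop(Z %*% fit$b), -PI_CLIP), PI_CLIP)
  mean(1 - stats::plogis(lp))
}

#' Backward variable selection for a mixture cure model
#'
#' Iteratively refits the model, each round removing the term (from either
#' the incidence or the latency part) with the largest Wald p-value above
#' `alpha`, until every remaining term is significant at `alpha`.
#' Intercepts and the Weibull scale are never candidates.  A candidate
#' whose removal makes the refit fail is skipped with a warning.
#'
#' @param data a [survival_dataset()].
#' @param spec the full starting [cure_spec()].
#' @param alpha Wald significance level to retain a term (default 0.05).
#' @param ... passed to [fit_pmcm()].
#' @return The selected [cure_spec()], with the final fit attached as
#'   attribute `"fit"`.
#' @export
backward_select <- function(data, spec, alpha = 0.05, ...) {
  cur <- spec
  fit <- fit_pmcm(data, cur, ...)
  skip <- character(0)
  repeat {
    st <- summary(fit)$table
    cand <- data.frame(
      part = c(rep("incidence", length(cur$incidence)),
               rep("latency", length(cur$latency))),
      term = c(cur$incidence, cur$latency),
      key = c(paste0("inc:", cur$incidence), paste0("lat:", cur$latency)),
      stringsAsFactors = FALSE)
    if (!nrow(cand)) break
    cand$p <- st[cand$key, "p_value"]
    cand <- cand[!(paste(cand$part, cand$term) %in% skip), , drop = FALSE]
    cand <- cand[order(-cand$p), , drop = FALSE]
    if (!nrow(cand) || cand$p[1] <= alpha) break
    worst <- cand[1, ]
    trial <- cur
    trial[[worst$part]] <- setdiff(trial[[worst$part]], worst$term)
    newfit <- tryCatch(fit_pmcm(data, trial, ...), error = function(e) NULL)
    if (is.null(newfit) || !newfit$converged) {
      warning("refit without ", worst$part, " term '", worst$term,
              "' failed to converge; keeping the term")
      skip <- c(skip, paste(worst$part, worst$term))
      next
    }
    cur <- trial
    fit <- newfit
  }
  attr(cur, "fit") <- fit
  cur
}
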