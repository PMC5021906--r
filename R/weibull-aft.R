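## Censored Weibull accelerated-failure-time fitting.
##
## Parameterization: log T = X beta + sigma W with W standard minimum
## extreme value, so S(t | x) = exp(-exp(w)), w = (log t - x'beta)/sigma.
## The working parameter vector is (beta, theta = log sigma), which keeps
## the optimization unconstrained.  A hand-rolled Newton fitter is used
## (rather than delegating to survreg) because the tree machinery needs
## per-subject score contributions and very cheap warm-started refits
## during the exhaustive split search; survreg serves as an independent
## cross-check in the test suite.

weibull_loglik_parts <- function(beta, theta, logt, event, X) {
  sigma <- exp(theta)
  w <- (logt - drop(X %*% beta)) / sigma
  ew <- exp(w)
  ll <- ifelse(event == 1, -theta - logt + w - ew, -ew)
  list(ll = sum(ll), w = w, ew = ew, sigma = sigma)
}

weibull_grad <- function(parts, event, X) {
  gb <- crossprod(X, (parts$ew - event) / parts$sigma)
  gt <- sum(parts$w * parts$ew - event * (parts$w + 1))
  c(gb, gt)
}

weibull_hessian <- function(parts, event, X) {
  w <- parts$w; ew <- parts$ew; s <- parts$sigma
  Hbb <- -crossprod(X * (ew / s^2), X)
  Hbt <- -crossprod(X, (ew * (w + 1) - event) / s)
  Htt <- -sum(w * ew * (1 + w) - event * w)
  rbind(cbind(Hbb, Hbt), c(Hbt, Htt))
}

#' Fit a censored Weibull accelerated-failure-time model
#'
#' Maximum-likelihood fit of `log T = X beta + sigma W` (W standard minimum
#' extreme value) to right-censored data by Newton-Raphson with analytic
#' gradient and Hessian and step halving.  The scale is optimized on the
#' log scale, so the fit is unconstrained.
#'
#' @param time positive follow-up times (event times must be > 0).
#' @param event 0/1 event indicator; at least one event is required.
#' @param X design matrix including an intercept column.
#' @param init optional warm start `c(beta, log sigma)`.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#'
#' @return List with `beta`, `sigma`, `theta` (= log sigma), `loglik`,
#'   `converged`, `n`, `n_events` and the working-scale parameter vector
#'   `par`.
#' @seealso [fit_weibull_node()] for the tree-facing wrapper that also
#'   computes per-subject scores.
#' @export
weibull_aft_fit <- function(time, event, X, init = NULL,
                            max_iter = 50L, tol = 1e-9) {
  n <- length(time)
  stopifnot(nrow(X) == n, length(event) == n)
  if (!any(event == 1))
    stop("no events in subset: censored-Weibull likelihood has no maximum")
  if (any(time[event == 1] <= 0))
    stop("event times must be strictly positive")
  logt <- log(pmax(time, .Machine$double.xmin))
  p <- ncol(X)

  if (is.null(init)) {
    ## crude start: least squares on log time of the events, scale from
    ## the residual spread (floored away from zero)
    evi <- event == 1
    beta0 <- tryCatch(qr.coef(qr(X[evi, , drop = FALSE]), logt[evi]),
                      error = function(e) rep(0, p))
    beta0[is.na(beta0)] <- 0
    r <- logt[evi] - drop(X[evi, , drop = FALSE] %*% beta0)
    s0 <- max(stats::sd(r), 0.1)
    if (!is.finite(s0)) s0 <- 1
    par <- c(beta0, log(s0))
  } else {
    stopifnot(length(init) == p + 1L)
    par <- init
  }
  par <- unname(par)

  parts <- weibull_loglik_parts(par[seq_len(p)], par[p + 1L], logt, event, X)
  ll <- parts$ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- weibull_grad(parts, event, X)
    if (sqrt(sum(g^2)) < tol * (1 + abs(ll))) { converged <- TRUE; break }
    H <- weibull_hessian(parts, event, X)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) step <- g  # gradient ascent
    ## step halving: accept the first non-decreasing candidate
    improved <- FALSE
    for (h in 0:25) {
      cand <- par + step / 2^h
      pc <- weibull_loglik_parts(cand[seq_len(p)], cand[p + 1L],
                                 logt, event, X)
      if (is.finite(pc$ll) && pc$ll > ll - 1e-12) {
        par <- cand; parts <- pc; ll <- pc$ll; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  if (!converged) {
    ## Newton stalled (near-flat or badly scaled likelihood, e.g. heavily
    ## censored cure-mixture subsets): fall back to quasi-Newton ascent,
    ## then polish with a final Newton pass
    opt <- tryCatch(stats::optim(
      par,
      fn = function(z) -weibull_loglik_parts(z[seq_len(p)], z[p + 1L],
                                             logt, event, X)$ll,
      gr = function(z) -weibull_grad(
        weibull_loglik_parts(z[seq_len(p)], z[p + 1L], logt, event, X),
        event, X),
      method = "BFGS", control = list(maxit = 200L, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value >= ll) {
      par <- unname(opt$par)
      parts <- weibull_loglik_parts(par[seq_len(p)], par[p + 1L],
                                    logt, event, X)
      ll <- parts$ll
      for (iter in seq_len(10L)) {
        g <- weibull_grad(parts, event, X)
        if (sqrt(sum(g^2)) < tol * (1 + abs(ll))) break
        H <- weibull_hessian(parts, event, X)
        step <- tryCatch(solve(H, -g), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) break
        cand <- par + step
        pc <- weibull_loglik_parts(cand[seq_len(p)], cand[p + 1L],
                                   logt, event, X)
        if (!is.finite(pc$ll) || pc$ll < ll - 1e-10) break
        par <- cand; parts <- pc; ll <- pc$ll
      }
    }
    g <- weibull_grad(parts, event, X)
    converged <- sqrt(sum(g^2)) < 1e-4 * (1 + abs(ll))
  }
  par <- unname(par)
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  list(beta = beta, theta = par[p + 1L], sigma = exp(par[p + 1L]),
       loglik = ll, par = par, converged = converged,
       n = n, n_events = sum(event == 1))
}

#' Per-subject score contributions of a censored Weibull AFT fit
#'
#' Evaluates, at the fitted parameters, each subject's contribution to the
#' gradient of the log-likelihood with respect to the working parameters
#' `(beta, log sigma)`.  These are the empirical estimating-function values
#' that drive the parameter-instability tests: at an interior optimum their
#' column sums vanish.
#'
#' @param fit result of [weibull_aft_fit()].
#' @param time,event,X the data the fit was computed on.
#' @return numeric matrix, one row per subject, `ncol(X) + 1` columns.
#' @export
weibull_scores <- function(fit, time, event, X) {
  logt <- log(pmax(time, .Machine$double.xmin))
  p <- ncol(X)
  parts <- weibull_loglik_parts(fit$par[seq_len(p)], fit$par[p + 1L],
                                logt, event, X)
  sc_eta <- (parts$ew - event) / parts$sigma          # d ll_i / d eta_i
  sc_theta <- parts$w * parts$ew - event * (parts$w + 1)
  out <- cbind(X * sc_eta, sc_theta)
  colnames(out) <- c(colnames(X), "log(sigma)")
  out
}
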