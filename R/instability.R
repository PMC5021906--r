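## Score-based parameter-instability (fluctuation) tests.
##
## Given per-subject score contributions of a fitted node model, the tests
## ask whether the parameters are stable across the ordering induced by a
## partitioning variable.  Numeric variables use the sup of the quadratic
## form of the decorrelated cumulative score process (supLM); categorical
## variables aggregate scores within levels into a chi-square statistic.

## cache of Monte-Carlo null distributions for the supLM statistic,
## keyed by (k, trim); the simulation uses its own fixed seed so p-values
## are deterministic and the caller's RNG state is untouched
.suplm_cache <- new.env(parent = emptyenv())

suplm_null_sample <- function(k, trim, n_grid = 400L, n_sim = 5000L) {
  key <- paste(k, format(trim), n_grid, n_sim, sep = "|")
  if (!is.null(.suplm_cache[[key]])) return(.suplm_cache[[key]])
  sup <- with_preserved_seed(760513L + k, {
    tt <- (seq_len(n_grid)) / (n_grid + 1L)
    keep <- tt >= trim & tt <= 1 - trim
    acc <- matrix(0, sum(keep), n_sim)
    for (j in seq_len(k)) {
      inc <- matrix(stats::rnorm(n_grid * n_sim, sd = sqrt(1 / (n_grid + 1L))),
                    n_grid, n_sim)
      W <- apply(inc, 2, cumsum)
      B <- W - outer(tt, W[n_grid, ])        # Brownian bridge (approx.)
      acc <- acc + B[keep, , drop = FALSE]^2
    }
    wgt <- tt[keep] * (1 - tt[keep])
    apply(acc / wgt, 2, max)
  })
  .suplm_cache[[key]] <- sort(sup)
  sup
}

## symmetric inverse square root with ridge jitter when near-singular
inv_sqrt_info <- function(J) {
  ee <- eigen((J + t(J)) / 2, symmetric = TRUE)
  tol <- max(ee$values, 0) * 1e-10
  vals <- ee$values
  if (any(vals <= tol)) vals <- vals + 1e-8 * max(mean(vals), 1)
  ee$vectors %*% (t(ee$vectors) / sqrt(pmax(vals, 1e-300)))
}

#' Parameter-instability test along one partitioning variable
#'
#' Tests the null hypothesis that the node model's parameters are constant
#' across the subjects, against ordered instability along `part_var`.
#' For a numeric variable the statistic is
#' `sup_j ||B_j||^2 / (t_j (1 - t_j))` where `B_j` is the decorrelated
#' cumulative sum of scores up to rank `j` (taken only at boundaries
#' between distinct values, within a trimmed central range); its p-value
#' comes from the asymptotic Brownian-bridge null distribution, evaluated
#' by a cached Monte-Carlo approximation.  For a factor the statistic
#' aggregates scores within levels into a chi-square with
#' `k * (levels - 1)` degrees of freedom.  Scores are decorrelated with
#' the outer-product-of-scores information estimate (ridge jitter when
#' singular).
#'
#' @param scores numeric matrix of per-subject score contributions (one
#'   row per subject), e.g. from [fit_weibull_node()].
#' @param part_var the partitioning variable's values on the same
#'   subjects; a factor/character is treated as categorical, anything
#'   numeric as ordered.
#' @param variable name to record (default deparsed).
#' @param trim fraction of the ordered sample trimmed from each end
#'   before taking the sup (numeric variables; default 0.1).
#' @param n_levels_adjust number of partitioning variables tested at the
#'   node, used for the Bonferroni adjustment (default 1).
#' @return An object of class `"instability_record"`: list with
#'   `variable`, `statistic`, `p_value`, `p_adjusted`, `test_kind`.
#' @export
parameter_instability_test <- function(scores, part_var,
                                       variable = deparse(substitute(part_var)),
                                       trim = 0.1,
                                       n_levels_adjust = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(part_var) == n, n >= 2L)
  categorical <- is.factor(part_var) || is.character(part_var) ||
    is.logical(part_var)

  if (length(unique(part_var)) < 2L) {
    return(new_instability_record(variable, 0, 1, n_levels_adjust,
                                  if (categorical) "categorical-fluctuation"
                                  else "sup-fluctuation"))
  }

  k <- ncol(scores)
  sc <- scale(scores, center = TRUE, scale = FALSE)   # guard tiny drift
  J <- crossprod(sc) / n
  Ji <- inv_sqrt_info(J)

  if (categorical) {
    f <- factor(part_var)
    L <- nlevels(f)
    stat <- 0
    for (l in levels(f)) {
      idx <- f == l
      wl <- mean(idx)
      zl <- drop(crossprod(Ji, colSums(sc[idx, , drop = FALSE]))) / sqrt(n)
      stat <- stat + sum(zl^2) / wl
    }
    p <- stats::pchisq(stat, df = k * (L - 1L), lower.tail = FALSE)
    return(new_instability_record(variable, stat, p, n_levels_adjust,
                                  "categorical-fluctuation"))
  }

  ord <- order(part_var)
  v <- part_var[ord]
  proc <- apply(sc[ord, , drop = FALSE] %*% t(Ji), 2, cumsum) / sqrt(n)
  tj <- seq_len(n) / n
  ## evaluate only at boundaries between distinct values, inside the trim
  boundary <- c(v[-n] < v[-1L], FALSE)
  keep <- boundary & tj >= trim & tj <= 1 - trim
  if (!any(keep))
    return(new_instability_record(variable, 0, 1, n_levels_adjust,
                                  "sup-fluctuation"))
  qf <- rowSums(proc[keep, , drop = FALSE]^2) / (tj[keep] * (1 - tj[keep]))
  stat <- max(qf)
  null <- suplm_null_sample(k, trim)
  p <- (sum(null >= stat) + 1) / (length(null) + 1)
  new_instability_record(variable, stat, p, n_levels_adjust,
                         "sup-fluctuation")
}

new_instability_record <- function(variable, statistic, p, m, kind) {
  structure(list(variable = variable, statistic = statistic,
                 p_value = p,
                 p_adjusted = min(1, p * m),
                 test_kind = kind),
            class = "instability_record")
}

#' @export
print.instability_record <- function(x, ...) {
  cat(sprintf("%s: %s stat = %.3f, p = %.4g (Bonferroni-adjusted %.4g)\n",
              x$variable, x$test_kind, x$statistic, x$p_value, x$p_adjusted))
  invisible(x)
}
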