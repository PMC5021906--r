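#' Right-censored survival dataset with covariate roles
#'
#' Bundles a data frame of one row per subject with the names of its
#' follow-up-time and event-indicator columns and a role assignment for the
#' covariate columns.  Roles distinguish covariates entering the latency
#' (Weibull) part of a cure model, the incidence (logistic) part, and the
#' partitioning variables offered to a model-based tree; a column may hold
#' several roles.
#'
#' @param data data frame, one row per subject.
#' @param time name of the follow-up-time column (nonnegative numeric).
#' @param event name of the event-indicator column, coded 1 = event
#'   observed, 0 = right-censored.
#' @param latency,incidence,partitioning character vectors of covariate
#'   column names (possibly empty, possibly overlapping).
#'
#' @return An object of class `"survival_dataset"`: a list with elements
#'   `data`, `time`, `event` and `roles` (a named list of the three role
#'   vectors).
#'
#' @examples
#' d <- data.frame(t = c(1, 2, 3), d = c(1, 0, 1), x = c(0.1, 0.5, 0.9))
#' sd <- survival_dataset(d, time = "t", event = "d", latency = "x")
#' nrow(sd$data)
#' @export
survival_dataset <- function(data, time = "time", event = "event",
                             latency = character(), incidence = character(),
                             partitioning = character()) {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(names(data)))
    stop("column names must be unique")
  roles <- list(latency = as.character(latency),
                incidence = as.character(incidence),
                partitioning = as.character(partitioning))
  obj <- structure(list(data = data, time = time, event = event,
                        roles = roles),
                   class = "survival_dataset")
  validate_survival_dataset(obj, require_event = FALSE)
  obj
}

#' Validate a survival dataset
#'
#' Checks the invariants every fitting routine relies on: the mapped
#' columns exist, times are nonnegative, the event indicator is strictly
#' {0, 1}, and no mapped column contains missing values.
#'
#' @param x a [survival_dataset()].
#' @param require_event if `TRUE` (the default of the fitting routines)
#'   at least one observed event is required; likelihood evaluation and
#'   plain construction do not need one.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_survival_dataset <- function(x, require_event = TRUE) {
  stopifnot(inherits(x, "survival_dataset"))
  used <- unique(c(x$time, x$event, unlist(x$roles)))
  missing_cols <- setdiff(used, names(x$data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  tm <- x$data[[x$time]]
  ev <- x$data[[x$event]]
  if (!is.numeric(tm)) stop("time column '", x$time, "' must be numeric")
  for (cl in used) {
    if (anyNA(x$data[[cl]]))
      stop("missing values in mapped column '", cl, "'")
  }
  if (any(tm < 0)) stop("negative follow-up times are not allowed")
  if (!all(ev %in% c(0, 1))) stop("event column '", x$event,
                                  "' must be coded 0/1")
  if (require_event && !any(ev == 1))
    stop("at least one observed event is required")
  invisible(x)
}

#' @export
print.survival_dataset <- function(x, ...) {
  ev <- x$data[[x$event]]
  cat(sprintf("Survival dataset: %d subjects, %d events (%.1f%% censored)\n",
              nrow(x$data), sum(ev == 1), 100 * mean(ev == 0)))
  for (r in names(x$roles)) {
    if (length(x$roles[[r]]))
      cat(sprintf("  %-12s %s\n", paste0(r, ":"),
                  paste(x$roles[[r]], collapse = ", ")))
  }
  invisible(x)
}

## design matrix with intercept for a set of covariate columns;
## rank-deficiency is reported with the offending columns named
model_matrix_roles <- function(sd, terms, label = "model") {
  n <- nrow(sd$data)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(terms)) {
    M <- as.matrix(as.data.frame(lapply(sd$data[terms], as.numeric)))
    colnames(M) <- terms
    X <- cbind(X, M)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    stop("rank-deficient ", label, " design; collinear column(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  X
}
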