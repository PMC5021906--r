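## Data ingestion and report rendering.  The package's user surface is
## its R functions; these helpers cover the common round trips: delimited
## survival tables in, JSON/text/CSV summaries out.

#' Read a delimited survival table into a validated dataset
#'
#' Reads a CSV/TSV file with a header, maps the named columns onto the
#' [survival_dataset()] contract, recodes the event column bit-exactly
#' to 0/1 via `event_labels`, and drops rows with missing values in any
#' mapped column (reporting how many).
#'
#' @param path file path.
#' @param time,event names of the time and event columns.
#' @param latency,incidence,partitioning covariate role assignments.
#' @param event_labels named vector mapping the file's event codes onto
#'   0/1, e.g. `c(dead = 1, alive = 0)`; `NULL` (default) expects the
#'   column to already be 0/1.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @return A [survival_dataset()].
#' @export
read_survival_csv <- function(path, time, event,
                              latency = character(),
                              incidence = character(),
                              partitioning = character(),
                              event_labels = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mapped <- unique(c(time, event, latency, incidence, partitioning))
  missing_cols <- setdiff(mapped, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df[[time]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[time]]))) &
                   !is.na(df[[time]]))
    stop("non-numeric time value in data row ",
         if (length(bad)) bad[1] else "?")
  }
  neg <- which(df[[time]] < 0)
  if (length(neg))
    stop("negative time in data row ", neg[1])
  if (!is.null(event_labels)) {
    ev <- df[[event]]
    unknown <- setdiff(unique(ev[!is.na(ev)]), names(event_labels))
    if (length(unknown))
      stop("event value(s) not covered by event_labels: ",
           paste(unknown, collapse = ", "))
    df[[event]] <- as.numeric(event_labels[as.character(ev)])
  }
  keep <- stats::complete.cases(df[, mapped, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values in mapped columns ",
            "dropped (", sum(keep), " retained)")
  survival_dataset(df[keep, , drop = FALSE], time = time, event = event,
                   latency = latency, incidence = incidence,
                   partitioning = partitioning)
}

pmcm_fit_to_list <- function(fit) {
  st <- summary(fit)$table
  list(model = "logistic-weibull-mixture-cure",
       coefficients = lapply(rownames(st), function(r) list(
         term = r, estimate = st[r, "estimate"], se = st[r, "se"],
         ci_lower = st[r, "lower"], ci_upper = st[r, "upper"],
         p_value = st[r, "p_value"])),
       loglik = fit$loglik, aic = fit$aic, n = fit$n,
       n_events = fit$n_events, converged = fit$converged,
       boundary = fit$boundary)
}

node_to_list <- function(node) {
  out <- list(id = node$id, n = node$fit$n, n_events = node$fit$n_events,
              coefficients = as.list(node$fit$beta),
              sigma = node$fit$sigma, loglik = node$fit$loglik,
              terminal = node$terminal)
  if (!is.null(node$instability))
    out$instability <- node$instability
  if (!node$terminal) {
    out$split <- node$split[setdiff(names(node$split), "searched")]
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

mob_tree_to_list <- function(tree) {
  list(model = "weibull-model-based-partitioning",
       n = tree$n, n_terminal = n_terminal_nodes(tree),
       aic = tree_aic(tree),
       config = unclass(tree$config),
       root = node_to_list(tree$root))
}

#' Write analysis results to an output directory
#'
#' Renders whatever results are supplied: a cure-model fit as JSON plus an
#' aligned-text coefficient table (estimate, SE, 95% CI, p-value, AIC,
#' estimated cure fraction when the data are supplied), a partitioning
#' tree as JSON plus indented text, a Kaplan-Meier estimate as a step CSV,
#' and always a `manifest.json` recording the seed and package version.
#' Outputs carry no timestamps, so a rerun with identical inputs is
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param fit optional `"pmcm_fit"`.
#' @param tree optional `"mob_tree"`.
#' @param km optional `"step_survival"`.
#' @param data optional [survival_dataset()] used to add the estimated
#'   cure fraction to the fit summary.
#' @param seed seed to record in the manifest.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(out_dir, fit = NULL, tree = NULL, km = NULL,
                          data = NULL, seed = NA) {
  if (is.null(fit) && is.null(tree) && is.null(km))
    stop("nothing to render: supply at least one result")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character(0)

  if (!is.null(fit)) {
    p <- file.path(out_dir, "cure_model_fit.json")
    jsonlite::write_json(pmcm_fit_to_list(fit), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "cure_model_fit.txt")
    txt <- c(utils::capture.output(print(summary(fit))),
             if (!is.null(data))
               sprintf("Estimated cure fraction = %.4f",
                       estimated_cure_fraction(fit, data)))
    writeLines(txt, p)
    paths <- c(paths, p)
  }
  if (!is.null(tree)) {
    p <- file.path(out_dir, "mob_tree.json")
    jsonlite::write_json(mob_tree_to_list(tree), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "mob_tree.txt")
    writeLines(utils::capture.output(print(tree)), p)
    paths <- c(paths, p)
  }
  if (!is.null(km)) {
    p <- file.path(out_dir, "kaplan_meier.csv")
    utils::write.csv(as.data.frame(km), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(package = "curemob",
                   version = as.character(utils::packageVersion("curemob")),
                   seed = seed,
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
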