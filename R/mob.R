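## Model-based recursive partitioning with censored-Weibull node models.
##
## The growing loop at each node: (1) fit the Weibull node model, (2) test
## parameter stability along every partitioning variable with Bonferroni
## correction, (3) if any adjusted p-value falls below alpha, split on the
## most unstable variable at the cutpoint minimizing the children's summed
## negative log-likelihood, (4) recurse.  Overfitting is controlled by the
## Bonferroni prepruning and optional bottom-up AIC postpruning.

#' Tree-growing configuration
#'
#' @param alpha prepruning significance level for the Bonferroni-adjusted
#'   instability tests (default 0.05).
#' @param min_node_size minimum subjects per child node (default 20).
#' @param max_depth optional depth cap (root has depth 0; `Inf` = none).
#' @param postprune `"AIC"` to collapse splits that do not pay their AIC
#'   penalty, `"none"` to keep the grown tree.
#' @param trim trimming fraction for the sup-type instability test.
#' @return An object of class `"mob_config"`.
#' @export
mob_config <- function(alpha = 0.05, min_node_size = 20L, max_depth = Inf,
                       postprune = c("AIC", "none"), trim = 0.1) {
  postprune <- match.arg(postprune)
  stopifnot(alpha > 0, alpha < 1, min_node_size >= 1)
  structure(list(alpha = alpha, min_node_size = as.integer(min_node_size),
                 max_depth = max_depth, postprune = postprune, trim = trim),
            class = "mob_config")
}

#' Fit the censored-Weibull node model on a subset
#'
#' Wraps [weibull_aft_fit()] and attaches the per-subject score
#' contributions needed by the instability tests.  The score columns sum
#' to approximately zero at the optimum.
#'
#' @param time,event survival columns of the subset.
#' @param X design matrix (intercept included) of the node regressors.
#' @param init optional warm start on the working scale.
#' @return An object of class `"weibull_node_fit"`: the
#'   [weibull_aft_fit()] fields plus `scores` (n x (p + 1) matrix) and
#'   `aic`.
#' @export
fit_weibull_node <- function(time, event, X, init = NULL) {
  fit <- weibull_aft_fit(time, event, X, init = init)
  fit$scores <- weibull_scores(fit, time, event, X)
  fit$k <- ncol(X) + 1L
  fit$aic <- 2 * fit$k - 2 * fit$loglik
  class(fit) <- "weibull_node_fit"
  fit
}

#' @export
print.weibull_node_fit <- function(x, ...) {
  cat(sprintf("Weibull node model: n = %d, events = %d, logLik = %.3f\n",
              x$n, x$n_events, x$loglik))
  print(c(x$beta, sigma = x$sigma), digits = 4)
  invisible(x)
}

## negative log-likelihood of a child candidate, or Inf if unfittable
child_negll <- function(time, event, X, init) {
  f <- tryCatch(weibull_aft_fit(time, event, X, init = init),
                error = function(e) NULL)
  if (is.null(f) || !is.finite(f$loglik)) list(negll = Inf, par = init)
  else list(negll = -f$loglik, par = f$par)
}

#' Exhaustive split-point search along one variable
#'
#' Scans every admissible cutpoint (midpoints between consecutive distinct
#' sorted values that leave at least `min_node_size` subjects and at least
#' one event on each side) and returns the one minimizing the sum of the
#' two children's negative log-likelihoods.  A factor is searched over all
#' binary partitions of its observed levels under the same objective.
#' Child fits are warm-started from the neighbouring candidate, so the
#' scan is fast despite being exhaustive.
#'
#' @param time,event survival columns of the node's subset.
#' @param X node-model design matrix on the subset.
#' @param v the splitting variable's values on the subset.
#' @param min_node_size minimum child size.
#' @param parent_par optional working-scale parent parameters used as the
#'   initial warm start.
#' @return `NULL` when no admissible split exists; otherwise a list with
#'   `cutpoint` (numeric threshold, `<=` goes left) or `left_levels`
#'   (factor case), `objective` (summed children negative log-likelihood),
#'   and the candidate table `searched`.
#' @export
find_split_point <- function(time, event, X, v, min_node_size = 20L,
                             parent_par = NULL) {
  n <- length(time)
  stopifnot(nrow(X) == n, length(v) == n)

  if (is.factor(v) || is.character(v)) {
    f <- factor(v)
    levs <- levels(droplevels(f))
    L <- length(levs)
    if (L < 2L) return(NULL)
    if (L > 12L) stop("too many factor levels for exhaustive partitioning")
    best <- NULL
    searched <- list()
    for (code in seq_len(2^(L - 1L) - 1L)) {
      left <- levs[bitwAnd(code, 2^(seq_len(L) - 1L)) > 0]
      li <- f %in% left
      if (sum(li) < min_node_size || sum(!li) < min_node_size) next
      if (!any(event[li] == 1) || !any(event[!li] == 1)) next
      ol <- child_negll(time[li], event[li], X[li, , drop = FALSE],
                        parent_par)
      or <- child_negll(time[!li], event[!li], X[!li, , drop = FALSE],
                        parent_par)
      obj <- ol$negll + or$negll
      searched[[length(searched) + 1L]] <-
        data.frame(partition = paste(left, collapse = "+"), objective = obj)
      if (is.finite(obj) && (is.null(best) || obj < best$objective))
        best <- list(left_levels = left, objective = obj)
    }
    if (is.null(best)) return(NULL)
    best$searched <- do.call(rbind, searched)
    return(best)
  }

  ord <- order(v)
  vs <- v[ord]; ts <- time[ord]; es <- event[ord]; Xs <- X[ord, , drop = FALSE]
  distinct_end <- which(vs[-n] < vs[-1L])          # last index of each value
  cum_ev <- cumsum(es)
  tot_ev <- cum_ev[n]
  admissible <- distinct_end[
    distinct_end >= min_node_size & (n - distinct_end) >= min_node_size &
      cum_ev[distinct_end] >= 1 & (tot_ev - cum_ev[distinct_end]) >= 1]
  if (!length(admissible)) return(NULL)

  best <- NULL
  pl <- parent_par; pr <- parent_par
  objs <- numeric(length(admissible))
  for (a in seq_along(admissible)) {
    j <- admissible[a]
    ol <- child_negll(ts[1:j], es[1:j], Xs[1:j, , drop = FALSE], pl)
    or <- child_negll(ts[(j + 1):n], es[(j + 1):n],
                      Xs[(j + 1):n, , drop = FALSE], pr)
    if (is.finite(ol$negll)) pl <- ol$par
    if (is.finite(or$negll)) pr <- or$par
    objs[a] <- ol$negll + or$negll
    if (is.finite(objs[a]) && (is.null(best) || objs[a] < best$objective))
      best <- list(cutpoint = (vs[j] + vs[j + 1L]) / 2, objective = objs[a])
  }
  if (is.null(best)) return(NULL)
  best$searched <- data.frame(
    cutpoint = (vs[admissible] + vs[admissible + 1L]) / 2,
    objective = objs)
  best
}

mob_next_id <- function(env) {
  env$id <- env$id + 1L
  env$id
}

mob_grow_node <- function(sd, idx, X_all, part_vars, config, depth, env) {
  time <- sd$data[[sd$time]][idx]
  event <- sd$data[[sd$event]][idx]
  X <- X_all[idx, , drop = FALSE]
  fit <- fit_weibull_node(time, event, X)
  node <- list(id = mob_next_id(env), idx = idx, fit = fit,
               instability = NULL, split = NULL, children = NULL,
               terminal = TRUE, depth = depth)

  if (depth >= config$max_depth || length(idx) < 2L * config$min_node_size)
    return(node)

  m <- length(part_vars)
  recs <- lapply(part_vars, function(pv) {
    parameter_instability_test(fit$scores, sd$data[[pv]][idx],
                               variable = pv, trim = config$trim,
                               n_levels_adjust = m)
  })
  node$instability <- data.frame(
    variable = vapply(recs, `[[`, "", "variable"),
    statistic = vapply(recs, `[[`, 0, "statistic"),
    p_value = vapply(recs, `[[`, 0, "p_value"),
    p_adjusted = vapply(recs, `[[`, 0, "p_adjusted"),
    test_kind = vapply(recs, `[[`, "", "test_kind"),
    stringsAsFactors = FALSE)

  best_i <- which.min(node$instability$p_adjusted)
  if (node$instability$p_adjusted[best_i] >= config$alpha) return(node)

  split_var <- part_vars[best_i]
  v <- sd$data[[split_var]][idx]
  sp <- find_split_point(time, event, X, v,
                         min_node_size = config$min_node_size,
                         parent_par = fit$par)
  if (is.null(sp)) return(node)

  if (!is.null(sp$cutpoint)) {
    li <- v <= sp$cutpoint
    node$split <- list(variable = split_var, cutpoint = sp$cutpoint,
                       objective = sp$objective)
  } else {
    li <- sd$data[[split_var]][idx] %in% sp$left_levels
    node$split <- list(variable = split_var, left_levels = sp$left_levels,
                       objective = sp$objective)
  }
  left <- mob_grow_node(sd, idx[li], X_all, part_vars, config, depth + 1L, env)
  right <- mob_grow_node(sd, idx[!li], X_all, part_vars, config,
                         depth + 1L, env)
  node$children <- list(left, right)
  node$terminal <- FALSE
  node
}

#' Grow a model-based recursive partitioning tree
#'
#' Recursively fits censored-Weibull node models, tests parameter
#' stability along each partitioning variable (Bonferroni-corrected over
#' the variables tested at the node), splits on the most unstable variable
#' at the negative-log-likelihood-optimal cutpoint, and stops when no
#' adjusted p-value falls below `alpha` or the size/depth limits bind.
#' With `postprune = "AIC"` (the default) the grown tree is then passed
#' through [prune_aic()].
#'
#' @param data a [survival_dataset()].
#' @param latency_terms covariate columns of the node model (may be empty
#'   for an intercept-only Weibull at each node).
#' @param partitioning character vector of partitioning variables; default
#'   the dataset's `partitioning` role.
#' @param config a [mob_config()].
#' @return An object of class `"mob_tree"`: recursive node list (each node
#'   carries `id`, row indices `idx`, a `"weibull_node_fit"`, the
#'   instability-test table, the split and children when internal) plus
#'   the growth metadata.  Ties at a numeric cutpoint go left
#'   (`<= cutpoint`).
#' @examples
#' set.seed(42)
#' d <- generate_cohort_like(400, scenario = "two_threshold")
#' tr <- grow_tree(d, latency_terms = character(),
#'                 config = mob_config(min_node_size = 30))
#' n_terminal_nodes(tr)
#' @export
grow_tree <- function(data, latency_terms = data$roles$latency,
                      partitioning = data$roles$partitioning,
                      config = mob_config()) {
  validate_survival_dataset(data)
  if (!length(partitioning)) stop("no partitioning variables given")
  overlap <- intersect(latency_terms, partitioning)
  if (length(overlap))
    warning("variable(s) used both as node regressor and partitioning ",
            "variable: ", paste(overlap, collapse = ", "))
  X_all <- model_matrix_roles(data, latency_terms, "node model")
  env <- new.env(); env$id <- 0L
  root <- mob_grow_node(data, seq_len(nrow(data$data)), X_all,
                        partitioning, config, 0L, env)
  tree <- structure(list(root = root, latency_terms = latency_terms,
                         partitioning = partitioning, config = config,
                         n = nrow(data$data)),
                    class = "mob_tree")
  if (config$postprune == "AIC") tree <- prune_aic(tree)
  tree
}

tree_walk <- function(node, fn) {
  fn(node)
  if (!node$terminal) for (ch in node$children) tree_walk(ch, fn)
  invisible(NULL)
}

terminal_nodes <- function(tree) {
  out <- list()
  tree_walk(tree$root, function(nd) {
    if (nd$terminal) out[[length(out) + 1L]] <<- nd
  })
  out
}

#' Number of terminal nodes of a tree
#' @param tree a `"mob_tree"`.
#' @return Integer count.
#' @export
n_terminal_nodes <- function(tree) length(terminal_nodes(tree))

count_splits <- function(tree) n_terminal_nodes(tree) - 1L

#' AIC of a fitted partitioning tree
#'
#' `AIC = 2k - 2 * sum(terminal log-likelihoods)` with
#' `k = (parameters per node model) * (terminal nodes) + (splits)`:
#' each estimated cutpoint is charged one parameter, so tree AICs are
#' comparable with single-model AICs and across trees of different sizes.
#'
#' @param tree a `"mob_tree"`.
#' @return The AIC value.
#' @export
tree_aic <- function(tree) {
  terms <- terminal_nodes(tree)
  ll <- sum(vapply(terms, function(nd) nd$fit$loglik, 0))
  p <- terms[[1]]$fit$k
  k <- p * length(terms) + (length(terms) - 1L)
  2 * k - 2 * ll
}

prune_node <- function(node, p_par) {
  if (node$terminal)
    return(list(node = node, loglik = node$fit$loglik, n_term = 1L))
  l <- prune_node(node$children[[1]], p_par)
  r <- prune_node(node$children[[2]], p_par)
  node$children <- list(l$node, r$node)
  sub_ll <- l$loglik + r$loglik
  sub_term <- l$n_term + r$n_term
  ## subtree AIC vs this node refitted as a terminal
  aic_sub <- 2 * (p_par * sub_term + (sub_term - 1L)) - 2 * sub_ll
  aic_here <- 2 * p_par - 2 * node$fit$loglik
  if (aic_sub > aic_here) {
    node$children <- NULL
    node$split <- NULL
    node$terminal <- TRUE
    return(list(node = node, loglik = node$fit$loglik, n_term = 1L))
  }
  list(node = node, loglik = sub_ll, n_term = sub_term)
}

#' AIC postpruning of a grown tree
#'
#' Bottom-up: every internal node whose subtree AIC exceeds the AIC of the
#' node refitted as a single terminal is collapsed.  The operation is
#' idempotent and never increases [tree_aic()].
#'
#' @param tree a `"mob_tree"`.
#' @return The pruned tree.
#' @export
prune_aic <- function(tree) {
  p <- tree$root$fit$k
  tree$root <- prune_node(tree$root, p)$node
  tree
}

#' Route a new observation to its terminal node
#'
#' Follows the fitted splits: at a numeric split, values `<= cutpoint` go
#' left; at a factor split, membership of the recorded left level set
#' decides.
#'
#' @param tree a `"mob_tree"`.
#' @param newdata a one-row data frame (or list) containing every split
#'   variable on the path.
#' @return List with `node_id` and the terminal `fit`.
#' @export
predict_terminal <- function(tree, newdata) {
  nd <- tree$root
  while (!nd$terminal) {
    v <- newdata[[nd$split$variable]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("split variable '", nd$split$variable, "' missing from newdata")
    go_left <- if (!is.null(nd$split$cutpoint)) v <= nd$split$cutpoint
               else as.character(v) %in% nd$split$left_levels
    nd <- nd$children[[if (go_left) 1L else 2L]]
  }
  list(node_id = nd$id, fit = nd$fit)
}

format_split <- function(split, side) {
  if (!is.null(split$cutpoint)) {
    op <- if (side == "left") "<=" else ">"
    sprintf("%s %s %.4g", split$variable, op, split$cutpoint)
  } else {
    lv <- if (side == "left") split$left_levels
          else paste0("not ", paste(split$left_levels, collapse = ","))
    sprintf("%s in {%s}", split$variable, paste(lv, collapse = ","))
  }
}

print_node <- function(node, indent, label) {
  pad <- strrep("  ", indent)
  est <- paste(sprintf("%s=%.3g", names(node$fit$beta), node$fit$beta),
               collapse = ", ")
  cat(sprintf("%s[%d] %s n=%d events=%d  %s, sigma=%.3g\n",
              pad, node$id, label, node$fit$n, node$fit$n_events,
              est, node$fit$sigma))
  if (!node$terminal) {
    print_node(node$children[[1]], indent + 1L,
               format_split(node$split, "left"))
    print_node(node$children[[2]], indent + 1L,
               format_split(node$split, "right"))
  }
}

#' @export
print.mob_tree <- function(x, ...) {
  cat(sprintf(
    "Model-based partitioning tree (Weibull nodes): %d terminal node(s), AIC = %.3f\n",
    n_terminal_nodes(x), tree_aic(x)))
  print_node(x$root, 0L, "root")
  invisible(x)
}
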