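test_that("split search agrees with cold brute force on small instances", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 60
    u <- runif(n)
    mu <- ifelse(u <= 0.5, 0, 1.5)
    t <- exp(mu + 0.6 * log(-log(runif(n))))
    cc <- rexp(n, 0.1)
    time <- pmin(t, cc); ev <- as.integer(t <= cc)
    X <- cbind(`(Intercept)` = rep(1, n))
    sp <- find_split_point(time, ev, X, u, min_node_size = 10)
    ## brute force: refit both children cold at every admissible cutpoint
    ord <- order(u); vs <- u[ord]; ts <- time[ord]; es <- ev[ord]
    cand <- which(vs[-n] < vs[-1])
    cumev <- cumsum(es)
    cand <- cand[cand >= 10 & (n - cand) >= 10 &
                   cumev[cand] >= 1 & (cumev[n] - cumev[cand]) >= 1]
    objs <- vapply(cand, function(j) {
      f1 <- weibull_aft_fit(ts[1:j], es[1:j], X[1:j, , drop = FALSE])
      f2 <- weibull_aft_fit(ts[(j + 1):n], es[(j + 1):n],
                            X[(j + 1):n, , drop = FALSE])
      -(f1$loglik + f2$loglik)
    }, 0)
    best_j <- cand[which.min(objs)]
    expect_equal(sp$cutpoint, (vs[best_j] + vs[best_j + 1]) / 2)
    expect_equal(sp$objective, min(objs), tolerance = 1e-8)
    ## chosen objective is minimal over everything searched
    expect_true(all(sp$objective <= sp$searched$objective + 1e-10))
  }
})

test_that("children's log-likelihoods sum to at least the parent's", {
  set.seed(42)
  d <- make_two_regime_data(500, jump = 1.5, extra_noise_vars = 1)
  tr <- grow_tree(d, latency_terms = character(),
                  config = mob_config(postprune = "none"))
  check_nested <- function(node) {
    if (node$terminal) return(invisible(NULL))
    ch_ll <- node$children[[1]]$fit$loglik + node$children[[2]]$fit$loglik
    expect_gte(ch_ll, node$fit$loglik - 1e-8)
    lapply(node$children, check_nested)
    invisible(NULL)
  }
  check_nested(tr$root)
})

test_that("children partition the parent's subset", {
  set.seed(43)
  d <- make_two_regime_data(400, jump = 2)
  tr <- grow_tree(d, latency_terms = character())
  check_part <- function(node) {
    if (node$terminal) return(invisible(NULL))
    l <- node$children[[1]]$idx; r <- node$children[[2]]$idx
    expect_length(intersect(l, r), 0)
    expect_setequal(c(l, r), node$idx)
    lapply(node$children, check_part)
    invisible(NULL)
  }
  check_part(tr$root)
  expect_gte(n_terminal_nodes(tr), 2)
})

test_that("a recovered single-threshold tree names the right variable", {
  set.seed(44)
  d <- make_two_regime_data(600, jump = 2, extra_noise_vars = 2)
  tr <- grow_tree(d, latency_terms = character())
  expect_identical(tr$root$split$variable, "u")
  expect_lt(abs(tr$root$split$cutpoint - 0.5), 0.1)
})

test_that("tree AIC follows the documented counting rule", {
  set.seed(45)
  d <- make_two_regime_data(400, jump = 2)
  tr <- grow_tree(d, latency_terms = character(),
                  config = mob_config(postprune = "none"))
  terms <- list()
  walk <- function(nd) {
    if (nd$terminal) terms[[length(terms) + 1]] <<- nd
    else lapply(nd$children, walk)
  }
  walk(tr$root)
  Tn <- length(terms)
  ll <- sum(vapply(terms, function(nd) nd$fit$loglik, 0))
  p <- 2  # intercept + log(sigma)
  expect_equal(tree_aic(tr), 2 * (p * Tn + (Tn - 1)) - 2 * ll)
  ## degenerate tree: AIC equals the root node fit's own AIC
  d2 <- make_homogeneous_data(200, n_noise = 1)
  set.seed(45)
  tr2 <- grow_tree(d2, latency_terms = character(),
                   config = mob_config(alpha = 1e-6))
  if (n_terminal_nodes(tr2) == 1)
    expect_equal(tree_aic(tr2), tr2$root$fit$aic)
})

test_that("AIC pruning is idempotent and never increases the AIC", {
  set.seed(46)
  d <- make_homogeneous_data(500, n_noise = 3)
  ## alpha = 0.5 invites spurious splits, pruning should clean up
  tr <- grow_tree(d, latency_terms = character(),
                  config = mob_config(alpha = 0.5, postprune = "none"))
  pr <- prune_aic(tr)
  expect_lte(tree_aic(pr), tree_aic(tr) + 1e-10)
  expect_lte(n_terminal_nodes(pr), n_terminal_nodes(tr))
  pr2 <- prune_aic(pr)
  expect_equal(n_terminal_nodes(pr2), n_terminal_nodes(pr))
  expect_equal(tree_aic(pr2), tree_aic(pr))
})

test_that("strong splits survive AIC pruning", {
  set.seed(47)
  d <- make_two_regime_data(500, jump = 2)
  tr <- grow_tree(d, latency_terms = character(),
                  config = mob_config(postprune = "none"))
  pr <- prune_aic(tr)
  expect_gte(n_terminal_nodes(pr), 2)
})

test_that("prediction routes training rows to their own terminal", {
  set.seed(48)
  d <- make_two_regime_data(400, jump = 2, extra_noise_vars = 1)
  tr <- grow_tree(d, latency_terms = character())
  terms <- new.env(); terms$map <- integer(nrow(d$data))
  walk <- function(nd) {
    if (nd$terminal) terms$map[nd$idx] <- nd$id
    else lapply(nd$children, walk)
  }
  walk(tr$root)
  for (i in sample(nrow(d$data), 25)) {
    pt <- predict_terminal(tr, d$data[i, ])
    expect_identical(pt$node_id, terms$map[[i]])
  }
  expect_error(predict_terminal(tr, data.frame(zzz = 1)),
               "missing")
})

test_that("a value exactly at the cutpoint goes to the left child", {
  set.seed(49)
  d <- make_two_regime_data(400, jump = 2)
  tr <- grow_tree(d, latency_terms = character())
  cut <- tr$root$split$cutpoint
  pt <- predict_terminal(tr, data.frame(u = cut))
  expect_identical(pt$node_id, tr$root$children[[1]]$id)
})

test_that("single-node trees predict the root for any row", {
  set.seed(50)
  d <- make_homogeneous_data(200, n_noise = 1)
  tr <- grow_tree(d, latency_terms = character(),
                  config = mob_config(alpha = 1e-4))
  if (n_terminal_nodes(tr) == 1) {
    pt <- predict_terminal(tr, data.frame(noise1 = 0))
    expect_identical(pt$node_id, tr$root$id)
  }
})

test_that("factor partitioning variables split by level subsets", {
  set.seed(51)
  n <- 450
  g <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  mu <- ifelse(g == "c", 1.8, 0)
  t <- exp(mu + 0.6 * log(-log(runif(n))))
  cc <- rexp(n, 0.1)
  df <- data.frame(time = pmin(t, cc), event = as.integer(t <= cc), g = g)
  d <- survival_dataset(df, latency = character(), partitioning = "g")
  tr <- grow_tree(d, latency_terms = character())
  expect_gte(n_terminal_nodes(tr), 2)
  sp <- tr$root$split
  expect_identical(sp$variable, "g")
  ## the isolated level set is {c} on one side
  expect_true(setequal(sp$left_levels, "c") ||
                setequal(sp$left_levels, c("a", "b")))
})
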