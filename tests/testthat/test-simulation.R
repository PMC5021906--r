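test_that("covariates have the stated distributions and are reproducible", {
  set.seed(71)
  cov <- generate_covariates(500)
  expect_equal(nrow(cov), 500)
  expect_lt(abs(mean(cov$z1)), 4 / sqrt(500))
  expect_true(all(cov$z2 >= 0 & cov$z2 <= 1))
  expect_true(all(cov$x >= 0 & cov$x <= 1))
  set.seed(71)
  expect_identical(generate_covariates(500), cov)
})

test_that("intercept calibration matches the analytic intercept-only case", {
  base <- generative_params(b1 = 0, b2 = 0)
  cal <- calibrate_intercepts(base, target_cure = 0.30,
                              target_censor = 0.40)
  expect_equal(cal$params$b0, log(0.7 / 0.3), tolerance = 1e-6)
})

test_that("cure rate zero gives the degenerate everyone-susceptible model", {
  cal <- calibrate_intercepts(generative_params(), 0, 0.40)
  expect_identical(cal$params$b0, Inf)
  set.seed(72)
  d <- simulate_dataset(cal$params, 400, cal$censor_rate_param)
  expect_true(all(attr(d, "latent")$U == 1))
})

test_that("infeasible targets are refused", {
  expect_error(calibrate_intercepts(generative_params(), 0.5, 0.3),
               "infeasible")
})

test_that("calibration hits its targets at large n", {
  set.seed(73)
  cal <- calibrate_intercepts(generative_params(), 0.30, 0.60)
  d <- simulate_dataset(cal$params, 50000, cal$censor_rate_param)
  lat <- attr(d, "latent")
  expect_lt(abs(mean(lat$U == 0) - 0.30), 0.01)
  expect_lt(abs(mean(d$data$event == 0) - 0.60), 0.02)
})

test_that("generated times follow the stated Weibull inversion law", {
  set.seed(74)
  ## rho = 1, eta = 0 (no covariate effect), everyone susceptible, no
  ## censoring: observed times are unit exponential
  p <- generative_params(b0 = Inf, c0 = 0, c1 = 0, rho = 1)
  d <- simulate_dataset(p, 5000, censor_rate_param = 0)
  expect_true(all(d$data$event == 1))
  ks <- suppressWarnings(ks.test(d$data$time, "pexp"))
  expect_gt(ks$p.value, 0.01)
  ## closed-form Weibull median at rho = 2
  set.seed(74)
  p2 <- generative_params(b0 = Inf, c0 = 0, c1 = 0, rho = 2)
  d2 <- simulate_dataset(p2, 20000, censor_rate_param = 0)
  expect_lt(abs(median(d2$data$time) - sqrt(log(2))), 0.02)
})

test_that("everyone-cured populations are entirely censored", {
  set.seed(75)
  p <- generative_params(b0 = -Inf)
  ## plogis(-Inf) = 0: all cured; exponential censoring supplies the
  ## observation times
  cov <- generate_covariates(200)
  pi <- plogis(p$b0 + p$b1 * cov$z1 + p$b2 * cov$z2)
  expect_true(all(pi == 0))
  d <- simulate_dataset(p, 200, censor_rate_param = 0.5, covariates = cov)
  expect_true(all(d$data$event == 0))
})

test_that("a reduced grid runs end to end and is deterministic", {
  cfgs <- list(sim_config(n = 120, censor_rate = 0.4, cure_rate = 0.15,
                          n_reps = 3, seed = 7),
               sim_config(n = 120, censor_rate = 0.6, cure_rate = 0.15,
                          interactions = TRUE, n_reps = 3, seed = 8))
  mc <- mob_config(min_node_size = 15)
  res <- suppressWarnings(run_simulation_grid(cfgs, mob_cfg = mc))
  expect_length(res, 2)
  for (r in res) {
    expect_true(is.finite(r$mean_pmcm_aic))
    expect_true(is.finite(r$mean_mob_aic))
    expect_equal(nrow(r$reps), 3)
  }
  res2 <- suppressWarnings(run_simulation_cell(cfgs[[1]], mob_cfg = mc))
  expect_identical(res2$reps, res[[1]]$reps)
})

test_that("the full study grid enumerates 36 shape-2 cells plus extras", {
  cfgs <- study_grid(n_reps = 1)
  rho2 <- Filter(function(c) c$rho == 2, cfgs)
  rho05 <- Filter(function(c) c$rho == 0.5, cfgs)
  expect_length(rho2, 36)   # 3 censor x 3 cure x 2 sizes x 2 structures
  expect_length(rho05, 18)  # extra shape-0.5 runs at the smaller size
  key <- sapply(cfgs, function(c)
    paste(c$n, c$censor_rate, c$cure_rate, c$rho, c$interactions))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(sapply(cfgs, function(c) c$censor_rate >= c$cure_rate)))
})

test_that("AIC table summaries match an independent pass over replicates", {
  set.seed(76)
  cfg <- sim_config(n = 150, censor_rate = 0.4, cure_rate = 0.15,
                    n_reps = 4, seed = 11)
  res <- run_simulation_cell(cfg, mob_cfg = mob_config(min_node_size = 15))
  tab <- summarize_aic_table(list(res))
  expect_equal(nrow(tab), 1)
  ok <- res$reps$pmcm_converged & is.finite(res$reps$pmcm_aic)
  expect_equal(tab$pmcm_aic, mean(res$reps$pmcm_aic[ok]), tolerance = 1e-9)
  ok2 <- res$reps$mob_converged & is.finite(res$reps$mob_aic)
  expect_equal(tab$mob_aic, mean(res$reps$mob_aic[ok2]), tolerance = 1e-9)
  txt <- format_aic_table(tab)
  expect_true(any(grepl("censor", txt)))
})

test_that("cohort-like generator produces a clinical-shaped table", {
  set.seed(77)
  d <- generate_cohort_like(539)
  expect_s3_class(d, "survival_dataset")
  for (b in c("er", "pr", "her2", "radio"))
    expect_true(all(d$data[[b]] %in% c(0, 1)))
  expect_true(all(d$data$tumor_size > 0))
  expect_true(all(d$data$nodes >= 0 & d$data$nodes == round(d$data$nodes)))
  expect_lt(abs(mean(d$data$event) - 0.37), 0.06)
})

test_that("two-threshold cohort truth is recoverable by the tree", {
  set.seed(78)
  hits <- 0L
  for (r in 1:10) {
    d <- generate_cohort_like(1000, scenario = "two_threshold")
    tr <- grow_tree(d, latency_terms = character(),
                    partitioning = c("tumor_size", "nodes"))
    if (n_terminal_nodes(tr) == 3) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})
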