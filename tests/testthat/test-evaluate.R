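# builds a minimal selection_experiment by hand so the estimator can be
# checked against hand counts
fake_experiment <- function(sel_lists, dgp = 2, n_vars = 20,
                            method = "stepwise") {
  m <- length(sel_lists)
  records <- data.frame(dgp = dgp, sigma_index = 1L, sigma = 1, rep = seq_len(m),
                        method = method, ok = TRUE)
  records$selected <- sel_lists
  records$pip <- vector("list", m)
  structure(
    list(records = records,
         datasets = data.frame(dgp = dgp, sigma_index = 1L, sigma = 1,
                               rep = seq_len(m), seed = seq_len(m),
                               t_x1 = NA_real_, t_x2 = NA_real_),
         grid = simulation_grid(n_vars = n_vars, n_reps = m),
         dgps = dgp, sigma_indices = 1L, methods = method,
         params = list(), n_failed = 0L),
    class = "selection_experiment")
}

get_est <- function(est, metric_, method_ = NULL) {
  r <- est[est$metric == metric_, ]
  if (!is.null(method_)) r <- r[r$method == method_, ]
  stopifnot(nrow(r) == 1)
  r
}

test_that("record counts and pairing follow the grid arithmetic", {
  g <- simulation_grid(n_reps = 10, base_seed = 5)
  ex <- run_experiment(g, dgps = 2, sigma_indices = 3,
                       methods = c("stepwise", "bma50", "bma95"))
  expect_equal(nrow(ex$records), 30)
  expect_equal(nrow(ex$datasets), 10)
  # paired design: all methods share the dataset seed per replicate
  expect_equal(length(unique(ex$records$rep)), 10)
  # the full study grid would be 5 x 30 x 300 datasets
  full <- simulation_grid()
  expect_equal(5 * length(full$sigmas) * full$n_reps, 45000)
})

test_that("identical base seeds give bit-identical experiments", {
  g <- simulation_grid(n_reps = 4, base_seed = 123)
  ex1 <- run_experiment(g, dgps = 4, sigma_indices = 2,
                        methods = c("stepwise", "bma50"))
  ex2 <- run_experiment(g, dgps = 4, sigma_indices = 2,
                        methods = c("stepwise", "bma50"))
  expect_identical(ex1$records$selected, ex2$records$selected)
  expect_identical(ex1$records$pip, ex2$records$pip)
  expect_identical(ex1$datasets, ex2$datasets)
  # a different master seed changes the data
  g2 <- simulation_grid(n_reps = 4, base_seed = 124)
  ex3 <- run_experiment(g2, dgps = 4, sigma_indices = 2,
                        methods = "stepwise")
  expect_false(identical(ex1$datasets$seed, ex3$datasets$seed))
})

test_that("probability estimates match hand counts on a fixture", {
  est <- estimate_selection_probabilities(
    fake_experiment(list(1L, c(1L, 5L), integer(0))))
  tr <- get_est(est, "true_selected")
  expect_equal(tr$estimate, 2 / 3, tolerance = 1e-12)
  expect_equal(tr$n, 3)
  expect_equal(tr$se, sqrt((2 / 3) * (1 / 3) / 3), tolerance = 1e-12)
  cm <- get_est(est, "correct_model")
  expect_equal(cm$estimate, 1 / 3, tolerance = 1e-12)
  rn <- get_est(est, "redundant_not_selected")
  # one redundant selection (x5) among 3 reps x 19 redundant variables
  expect_equal(rn$estimate, 1 - 1 / 57, tolerance = 1e-12)
  expect_equal(rn$n, 57)
})

test_that("a perfect selector scores 1 everywhere (and 0 on the indirect)", {
  est2 <- estimate_selection_probabilities(
    fake_experiment(rep(list(1L), 5), dgp = 2))
  expect_equal(get_est(est2, "true_selected")$estimate, 1)
  expect_equal(get_est(est2, "redundant_not_selected")$estimate, 1)
  expect_equal(get_est(est2, "correct_model")$estimate, 1)
  est5 <- estimate_selection_probabilities(
    fake_experiment(rep(list(1L), 5), dgp = 5))
  expect_equal(get_est(est5, "indirect_selected")$estimate, 0)
  est4 <- estimate_selection_probabilities(
    fake_experiment(rep(list(1L), 5), dgp = 4))
  expect_equal(get_est(est4, "correlated_redundant_not_selected")$estimate, 1)
  # DGP 3 reports pooled and per-predictor rows
  est3 <- estimate_selection_probabilities(
    fake_experiment(list(1:2, 1L, 1:2), dgp = 3))
  expect_equal(get_est(est3, "true_selected")$estimate, 5 / 6,
               tolerance = 1e-12)
  expect_equal(get_est(est3, "true_selected_x1")$estimate, 1)
  expect_equal(get_est(est3, "true_selected_x2")$estimate, 2 / 3,
               tolerance = 1e-12)
})

test_that("the redundant metric is per-variable, not any-variable", {
  # 2 reps each selecting a single (different) redundant variable under DGP1:
  # per-variable rate = 2 / (2 * 20); the any-variable reading would give 0
  est <- estimate_selection_probabilities(
    fake_experiment(list(7L, 12L), dgp = 1))
  expect_equal(get_est(est, "redundant_not_selected")$estimate,
               1 - 2 / 40, tolerance = 1e-12)
  # DGP1 has no true predictors: no true_selected row
  expect_false("true_selected" %in% est$metric)
})

test_that("empirical effect size tracks the sqrt(n)/sigma closed form", {
  g <- simulation_grid(n_reps = 5, base_seed = 9)
  ex <- run_experiment(g, dgps = 2, sigma_indices = c(1, 5, 10),
                       methods = "stepwise")
  eff <- compute_effect_size(ex)
  expect_equal(nrow(eff), 3)
  # DGP2 at sigma = 0.5: E|t| ~ sqrt(500)/0.5 ~ 44.7
  expect_equal(eff$effect_size[eff$sigma_index == 1], sqrt(500) / 0.5,
               tolerance = 0.15)
  # strictly decreasing across the sigma grid
  expect_true(all(diff(eff$effect_size[order(eff$sigma_index)]) < 0))
})

test_that("export writes a round-trippable CSV, manifest and figures", {
  g <- simulation_grid(n_reps = 3, base_seed = 77)
  ex <- run_experiment(g, dgps = c(2, 4), sigma_indices = c(1, 10),
                       methods = c("stepwise", "bma50"))
  out <- file.path(tempdir(), "stepbma-export")
  files <- export_results(ex, out)
  est <- estimate_selection_probabilities(ex)
  tab <- utils::read.csv(files[["estimates"]])
  expect_equal(nrow(tab), nrow(est))
  key <- function(d) paste(d$dgp, d$sigma_index, d$method, d$metric)
  tab <- tab[match(key(est), key(tab)), ]
  expect_equal(tab$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(tab$se, est$se, tolerance = 1e-12)
  man <- jsonlite::read_json(files[["manifest"]])
  expect_identical(man$base_seed, 77L)
  expect_identical(man$n_failed, 0L)
  for (f in files[3:6]) expect_true(file.exists(f))
  unlink(out, recursive = TRUE)
})
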