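test_that("posterior model probabilities follow the BIC weight formula", {
  mk <- function(bics) {
    data.frame(vars = I(as.list(seq_along(bics))), size = 1L,
               rss = NA_real_, bic = bics)
  }
  one <- posterior_model_probabilities(mk(3.7))
  expect_equal(one$posterior, 1)
  two <- posterior_model_probabilities(mk(c(10, 10)))
  expect_equal(two$posterior, c(0.5, 0.5))
  three <- posterior_model_probabilities(mk(c(0, 2, 4)))
  w <- exp(-c(0, 1, 2))
  expect_equal(sort(three$posterior, decreasing = TRUE),
               w / sum(w), tolerance = 1e-12)
  expect_equal(round(sort(three$posterior, decreasing = TRUE), 4),
               c(0.6652, 0.2447, 0.0900))
  empty <- data.frame(bic = numeric(0))
  empty$vars <- list()
  expect_error(posterior_model_probabilities(empty), "empty")
  # invariance to a constant shift of all BICs
  shifted <- posterior_model_probabilities(mk(c(0, 2, 4) + 123.4))
  expect_equal(shifted$posterior, three$posterior, tolerance = 1e-12)
})

test_that("Occam's window retains the ratio-test set and renormalizes", {
  post <- data.frame(size = c(1L, 1L, 2L))
  post$vars <- list(1L, 2L, c(1L, 2L))
  post$posterior <- c(0.65, 0.325, 0.025)  # 0.65/0.025 = 26 > 20
  class(post) <- c("bma_posterior", "data.frame")
  ret <- occams_window(post, C = 20)
  expect_equal(nrow(ret), 2)
  expect_equal(ret$posterior, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # vacuous window keeps everything unchanged
  all_ret <- occams_window(post, C = Inf)
  expect_equal(nrow(all_ret), 3)
  expect_equal(all_ret$posterior, post$posterior, tolerance = 1e-12)
  # best model always survives
  expect_true(any(vapply(ret$vars, identical, logical(1), 1L)))
})

test_that("strict mode removes supermodels dominated by a retained submodel", {
  post <- data.frame(size = c(1L, 2L, 1L))
  post$vars <- list(1L, c(1L, 2L), 3L)
  post$posterior <- c(0.5, 0.3, 0.2)
  class(post) <- c("bma_posterior", "data.frame")
  non_strict <- occams_window(post, C = 20, strict = FALSE)
  expect_equal(nrow(non_strict), 3)
  strict <- occams_window(post, C = 20, strict = TRUE)
  # {x1, x2} has the retained submodel {x1} with higher posterior -> removed
  expect_equal(nrow(strict), 2)
  expect_false(any(vapply(strict$vars, identical, logical(1), c(1L, 2L))))
  expect_equal(sum(strict$posterior), 1, tolerance = 1e-12)
  # strict result matches the plain-R oracle end to end
  ds <- make_toy(80, 6, beta = c(1, rep(0, 5)), sigma = 4, seed = 88)
  pip_strict <- bma_inclusion(ds, strict = TRUE, exhaustive = TRUE)
  expect_equal(as.numeric(pip_strict), r_exhaustive_bma(ds, strict = TRUE),
               tolerance = 1e-9)
})

test_that("inclusion probabilities sum retained posteriors per variable", {
  ret <- data.frame(size = c(1L, 2L))
  ret$vars <- list(1L, c(1L, 2L))
  ret$posterior <- c(0.7, 0.3)
  pip <- inclusion_probabilities(ret, 4)
  expect_equal(unname(pip), c(1.0, 0.3, 0, 0), tolerance = 1e-12)
  expect_named(pip, c("x1", "x2", "x3", "x4"))
  # un-normalized input is rejected
  ret$posterior <- c(0.7, 0.2)
  expect_error(inclusion_probabilities(ret, 4), "sum to 1")
})

test_that("model-space search equals exhaustive enumeration on small p", {
  ds <- make_toy(60, 5, beta = c(1, 0.5, 0, 0, 0), seed = 31)
  full <- search_model_space(ds, nbest = 32, max_size = 5)
  expect_equal(nrow(full), 2^5)
  # size-0 model always present
  expect_true(any(full$size == 0))
  # per-size RSS agrees with direct lm-based evaluation, and ordering holds
  for (k in 0:5) {
    rows <- full[full$size == k, ]
    oracle <- vapply(rows$vars, function(S) {
      f <- if (length(S)) lm(ds$y ~ ds$X[, S, drop = FALSE]) else lm(ds$y ~ 1)
      sum(residuals(f)^2)
    }, numeric(1))
    expect_equal(rows$rss, oracle, tolerance = 1e-8)
    expect_true(all(diff(rows$rss) >= -1e-10))
  }
  # dominant-predictor sanity: the best size-1 model is {x1}
  best1 <- full[full$size == 1, ][1, ]
  expect_identical(best1$vars[[1]], 1L)
})

test_that("pruned search reproduces the exhaustive pipeline exactly", {
  # end-to-end equivalence on p = 8..10 problems, including the plain-R oracle
  cases <- list(
    list(p = 8, beta = c(1, rep(0, 7)), sigma = 2, seed = 41),
    list(p = 10, beta = c(1, 0.5, rep(0, 8)), sigma = 1, seed = 42),
    list(p = 10, beta = rep(0, 10), sigma = 1, seed = 43))
  for (cs in cases) {
    ds <- make_toy(120, cs$p, beta = cs$beta, sigma = cs$sigma, seed = cs$seed)
    pip_fast <- bma_inclusion(ds)
    pip_exh <- bma_inclusion(ds, exhaustive = TRUE)
    expect_equal(as.numeric(pip_fast), as.numeric(pip_exh),
                 tolerance = 1e-9)
    expect_equal(as.numeric(pip_exh), r_exhaustive_bma(ds),
                 tolerance = 1e-9)
  }
})

test_that("selection is monotone in the threshold and propagates the pip", {
  ds <- simulate_dataset(make_dgp_spec(4), sigma = 8, seed = 55)
  s50 <- bma_select(ds, 0.5)
  s95 <- bma_select(ds, 0.95)
  expect_true(all(s95$selected %in% s50$selected))
  expect_identical(s50$selected, which(s50$pip >= 0.5))
  expect_identical(s95$selected, which(s95$pip >= 0.95))
  expect_equal(as.numeric(s50$pip), as.numeric(s95$pip),
               tolerance = 1e-12)
})

test_that("degenerate and invalid inputs are rejected", {
  ds <- make_toy(40, 3, seed = 61)
  expect_error(bma_select(ds, threshold = 0), "threshold")
  expect_error(bma_select(ds, threshold = 1), "threshold")
  expect_error(occams_window(
    structure(data.frame(posterior = 1), class = c("bma_posterior",
                                                   "data.frame")), C = 1))
  set.seed(62)
  X <- matrix(rnorm(90), 30, 3)
  X[, 3] <- X[, 1] - X[, 2]
  expect_error(search_model_space(as_sim_dataset(X, rnorm(30))),
               "rank deficient")
})
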