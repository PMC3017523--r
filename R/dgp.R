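#' Noise standard-deviation grid
#'
#' The study varies the effect size of the true predictor by varying the
#' residual standard deviation sigma over an arithmetic progression,
#' `sigma_k = sigma_min + increment * (k - 1)`. With the defaults this gives
#' 30 values 0.5, 3.24, 5.98, ..., 79.96. The stated endpoint "80" and the
#' increment 2.74 are mutually inconsistent in the fourth significant digit;
#' the increment is taken as authoritative, so the last value is 79.96.
#'
#' @param n_sigmas number of grid points (default 30)
#' @param sigma_min smallest noise standard deviation (default 0.5)
#' @param increment constant step between consecutive values (default 2.74)
#' @return numeric vector of length `n_sigmas`, strictly increasing
#' @examples
#' make_sigma_grid()[c(1, 30)]
#' @export
make_sigma_grid <- function(n_sigmas = 30, sigma_min = 0.5, increment = 2.74) {
  stopifnot(n_sigmas >= 1, sigma_min > 0, increment > 0)
  sigma_min + increment * (seq_len(n_sigmas) - 1)
}

#' Data-generating process specifications
#'
#' Five data-generating processes (DGPs) for an outcome conditioned on up to
#' two of 20 candidate predictors, `y = X beta + eps`, `eps ~ N(0, sigma^2)`:
#'
#' 1. null model: `beta_i = 0` for all i;
#' 2. one true predictor: `beta_1 = 1`;
#' 3. two true predictors: `beta_1 = beta_2 = 1`;
#' 4. one true predictor `beta_1 = 1` plus a correlated redundant variable:
#'    `x_2 = x_1 + N(0, 1)`;
#' 5. one true predictor `beta_1 = 1` generated from a redundant variable:
#'    `x_1 = x_2 + N(0, 1)`, making `x_2` an *indirect* predictor (related to
#'    the outcome only through `x_1`).
#'
#' In DGPs 4 and 5 the constructed column has variance 2 and correlation
#' `1/sqrt(2)` with its partner; all other columns are iid standard normal.
#'
#' @param dgp_id integer in 1..5
#' @param n_vars number of candidate predictors (default 20)
#' @return an object of class `dgp_spec`: list with `dgp_id`, `beta`
#'   (length `n_vars`), `true_set` (indices with nonzero beta),
#'   `correlated_redundant` (DGP 4: 2L, else NULL) and `indirect_predictor`
#'   (DGP 5: 2L, else NULL).
#' @examples
#' make_dgp_spec(3)$true_set
#' @export
make_dgp_spec <- function(dgp_id, n_vars = 20) {
  if (length(dgp_id) != 1 || is.na(dgp_id) || dgp_id %% 1 != 0 ||
      dgp_id < 1 || dgp_id > 5) {
    stop("`dgp_id` must be a single integer in 1..5, got: ",
         deparse(substitute(dgp_id)), " = ", paste(dgp_id, collapse = ","))
  }
  stopifnot(n_vars >= 2)
  dgp_id <- as.integer(dgp_id)
  beta <- numeric(n_vars)
  correlated_redundant <- NULL
  indirect_predictor <- NULL
  if (dgp_id == 2) beta[1] <- 1
  if (dgp_id == 3) beta[1:2] <- 1
  if (dgp_id == 4) { beta[1] <- 1; correlated_redundant <- 2L }
  if (dgp_id == 5) { beta[1] <- 1; indirect_predictor <- 2L }
  structure(
    list(dgp_id = dgp_id, beta = beta,
         true_set = which(beta != 0),
         correlated_redundant = correlated_redundant,
         indirect_predictor = indirect_predictor),
    class = "dgp_spec")
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat("Data-generating process", x$dgp_id, "\n")
  cat("  true predictors:",
      if (length(x$true_set)) paste0("x", x$true_set, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$correlated_redundant))
    cat("  correlated redundant variable: x", x$correlated_redundant,
        " = x1 + N(0,1)\n", sep = "")
  if (!is.null(x$indirect_predictor))
    cat("  indirect predictor: x", x$indirect_predictor,
        " (x1 = x2 + N(0,1))\n", sep = "")
  invisible(x)
}

#' Full simulation grid
#'
#' Bundles the design constants of the simulation study: 500 observations,
#' 20 candidate predictors, the 30-point sigma grid and 300 replicates per
#' (DGP, sigma) cell, plus the base seed from which all per-dataset seeds
#' are derived.
#'
#' @param n_obs observations per dataset (default 500)
#' @param n_vars candidate predictors (default 20)
#' @param sigmas noise grid (default [make_sigma_grid()])
#' @param n_reps replicates per cell (default 300)
#' @param base_seed integer master seed
#' @return object of class `simulation_grid`
#' @export
simulation_grid <- function(n_obs = 500, n_vars = 20,
                            sigmas = make_sigma_grid(),
                            n_reps = 300, base_seed = 1L) {
  stopifnot(n_obs > 0, n_vars > 0, n_reps > 0, all(sigmas > 0),
            length(base_seed) == 1, is.finite(base_seed))
  structure(
    list(n_obs = as.integer(n_obs), n_vars = as.integer(n_vars),
         sigmas = as.numeric(sigmas), n_reps = as.integer(n_reps),
         base_seed = as.integer(base_seed)),
    class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat("Simulation grid: n =", x$n_obs, "obs,", x$n_vars, "predictors,",
      length(x$sigmas), "sigma values in [", x$sigmas[1], ",",
      x$sigmas[length(x$sigmas)], "],", x$n_reps,
      "replicates per cell, base seed", x$base_seed, "\n")
  invisible(x)
}

#' Deterministic per-dataset seed
#'
#' Derives the RNG seed for one dataset from the master seed and the cell
#' coordinates by a chained multiply-mod hash,
#' `s <- (s * 69069 + key) mod (2^31 - 1)` over base seed, DGP id, sigma
#' index and replicate index. All intermediates stay below 2^53, so the
#' arithmetic is exact in doubles and the result is identical on every
#' platform. Within one master seed the map is injective in the replicate
#' index and (for the study's ranges) cell coordinates do not collide in
#' practice.
#'
#' @param base_seed master integer seed
#' @param dgp_id,sigma_index,rep_index cell coordinates (1-based)
#' @return integer in 0..(2^31 - 2)
#' @export
dataset_seed <- function(base_seed, dgp_id, sigma_index, rep_index) {
  m <- 2147483647  # 2^31 - 1
  s <- as.numeric(base_seed) %% m
  for (key in c(dgp_id, sigma_index, rep_index)) {
    s <- (s * 69069 + as.numeric(key)) %% m
  }
  as.integer(s)
}

#' Simulate one dataset from a data-generating process
#'
#' Draws an `n_obs x n_vars` matrix of iid standard-normal predictors, applies
#' the DGP's correlated construction if any (DGP 4: `x2 <- x1 + N(0,1)`;
#' DGP 5: `x1 <- x2 + N(0,1)`), and generates
#' `y = X beta + N(0, sigma^2)`. The draw order is fixed (X column-major,
#' then the construction noise, then the outcome noise), so a given seed
#' reproduces the dataset bit for bit.
#'
#' @param spec a [make_dgp_spec()] object
#' @param sigma residual standard deviation (> 0)
#' @param n_obs,n_vars dimensions; `n_obs >= n_vars + 2`
#' @param seed integer RNG seed for this dataset
#' @param rep_index optional replicate label carried along for bookkeeping
#' @return object of class `sim_dataset`: list with `X` (columns named
#'   `x1..xP`), `y`, `sigma`, `dgp_id`, `rep_index`, `seed`, `spec`
#' @examples
#' ds <- simulate_dataset(make_dgp_spec(2), sigma = 1, seed = 42)
#' dim(ds$X)
#' @export
simulate_dataset <- function(spec, sigma, n_obs = 500, n_vars = 20,
                             seed, rep_index = NA_integer_) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  if (n_obs < n_vars + 2) {
    stop("degenerate dimensions: need n_obs >= n_vars + 2 (got n_obs = ",
         n_obs, ", n_vars = ", n_vars, ")")
  }
  if (length(spec$beta) != n_vars) {
    stop("spec defines ", length(spec$beta), " coefficients but n_vars = ",
         n_vars)
  }
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n_obs * n_vars), n_obs, n_vars,
              dimnames = list(NULL, paste0("x", seq_len(n_vars))))
  if (spec$dgp_id == 4) X[, 2] <- X[, 1] + rnorm(n_obs)
  if (spec$dgp_id == 5) X[, 1] <- X[, 2] + rnorm(n_obs)
  y <- as.vector(X %*% spec$beta + rnorm(n_obs, 0, sigma))
  structure(
    list(X = X, y = y, sigma = sigma, dgp_id = spec$dgp_id,
         rep_index = as.integer(rep_index), seed = as.integer(seed),
         spec = spec),
    class = "sim_dataset")
}

#' Wrap an arbitrary (X, y) pair as a dataset
#'
#' Utility for applying the selectors to data not produced by
#' [simulate_dataset()] (toy problems, external data). No distributional
#' assumptions are attached.
#'
#' @param X numeric matrix of predictors
#' @param y numeric outcome vector, `length(y) == nrow(X)`
#' @return object of class `sim_dataset`
#' @export
as_sim_dataset <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), is.numeric(y), nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(
    list(X = X, y = as.numeric(y), sigma = NA_real_, dgp_id = NA_integer_,
         rep_index = NA_integer_, seed = NA_integer_, spec = NULL),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$X), "obs x", ncol(x$X), "predictors")
  if (!is.na(x$dgp_id))
    cat(", DGP", x$dgp_id, ", sigma =", x$sigma, ", seed =", x$seed)
  cat("\n")
  invisible(x)
}

#' Export a dataset as CSV plus a JSON sidecar
#'
#' Writes `y, x1..xP` as CSV and the provenance (dgp_id, sigma, replicate,
#' seed) as `<path>.json`. Intended for debugging and external re-analysis.
#'
#' @param dataset a `sim_dataset`
#' @param path output CSV path
#' @return invisibly, the two paths written
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  df <- data.frame(y = dataset$y, dataset$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(dgp_id = dataset$dgp_id, sigma = dataset$sigma,
         rep_index = dataset$rep_index, seed = dataset$seed),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
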