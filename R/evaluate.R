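#' Run the paired simulation experiment
#'
#' For every (DGP, sigma, replicate) cell: simulate one dataset from its
#' deterministic seed, fit the full model once (for the empirical effect-size
#' axis), and apply every requested selection method to that same dataset
#' (paired design). The BMA inclusion probabilities are computed once per
#' dataset and thresholded for both `bma50` and `bma95`.
#'
#' Individual fit failures are caught, logged, and recorded with `ok = FALSE`
#' — never silently dropped.
#'
#' @param grid a [simulation_grid()]
#' @param dgps DGP ids to simulate (default 1:5)
#' @param sigma_indices indices into `grid$sigmas` (default all)
#' @param methods subset of `c("stepwise", "bma50", "bma95")`
#' @param n_reps replicates per cell (default `grid$n_reps`)
#' @param alpha stepwise exclusion threshold (default 0.05)
#' @param C,strict,nbest,exhaustive BMA parameters, see [bma_select()]
#' @param progress print one line per (DGP, sigma) cell
#' @return object of class `selection_experiment`: list with
#'   `records` (data.frame: dgp, sigma_index, sigma, rep, method, ok,
#'   list-columns `selected` and `pip`), `datasets` (data.frame: one row per
#'   dataset with its seed and the full-model |t| of each true predictor),
#'   `grid`, `methods`, `params`, `n_failed`
#' @examples
#' g <- simulation_grid(n_reps = 2, base_seed = 7)
#' ex <- run_experiment(g, dgps = 2, sigma_indices = 1, methods = "stepwise")
#' nrow(ex$records)
#' @export
run_experiment <- function(grid, dgps = 1:5,
                           sigma_indices = seq_along(grid$sigmas),
                           methods = c("stepwise", "bma50", "bma95"),
                           n_reps = grid$n_reps,
                           alpha = 0.05, C = 20, strict = FALSE,
                           nbest = 150, exhaustive = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(grid, "simulation_grid"),
            all(dgps %in% 1:5),
            all(sigma_indices %in% seq_along(grid$sigmas)),
            n_reps >= 1)
  methods <- match.arg(methods, c("stepwise", "bma50", "bma95"),
                       several.ok = TRUE)
  need_bma <- any(c("bma50", "bma95") %in% methods)
  specs <- lapply(1:5, make_dgp_spec, n_vars = grid$n_vars)

  n_ds <- length(dgps) * length(sigma_indices) * n_reps
  n_rec <- n_ds * length(methods)
  rec_dgp <- integer(n_rec); rec_si <- integer(n_rec)
  rec_sigma <- numeric(n_rec); rec_rep <- integer(n_rec)
  rec_method <- character(n_rec); rec_ok <- logical(n_rec)
  rec_sel <- vector("list", n_rec); rec_pip <- vector("list", n_rec)
  ds_dgp <- integer(n_ds); ds_si <- integer(n_ds); ds_sigma <- numeric(n_ds)
  ds_rep <- integer(n_ds); ds_seed <- integer(n_ds)
  ds_t1 <- rep(NA_real_, n_ds); ds_t2 <- rep(NA_real_, n_ds)
  n_failed <- 0L
  i_rec <- 0L; i_ds <- 0L

  for (dgp in dgps) {
    spec <- specs[[dgp]]
    for (si in sigma_indices) {
      sigma <- grid$sigmas[si]
      if (progress) {
        message(sprintf("DGP %d  sigma %.2f  (%d reps)", dgp, sigma, n_reps))
      }
      for (r in seq_len(n_reps)) {
        seed <- dataset_seed(grid$base_seed, dgp, si, r)
        ds <- simulate_dataset(spec, sigma, grid$n_obs, grid$n_vars,
                               seed = seed, rep_index = r)
        i_ds <- i_ds + 1L
        ds_dgp[i_ds] <- dgp; ds_si[i_ds] <- si; ds_sigma[i_ds] <- sigma
        ds_rep[i_ds] <- r; ds_seed[i_ds] <- seed
        full <- tryCatch(fit_ols(ds, seq_len(grid$n_vars)),
                         error = function(e) NULL)
        if (!is.null(full) && length(spec$true_set) >= 1) {
          ds_t1[i_ds] <- abs(full$t_values[2])       # slope of x1
          if (length(spec$true_set) >= 2) {
            ds_t2[i_ds] <- abs(full$t_values[3])     # slope of x2 (DGP 3)
          }
        }
        pip <- NULL
        if (need_bma) {
          pip <- tryCatch(
            bma_inclusion(ds, C = C, strict = strict, nbest = nbest,
                          exhaustive = exhaustive),
            error = function(e) {
              message("BMA failed (dgp ", dgp, ", sigma ", sigma, ", rep ",
                      r, "): ", conditionMessage(e))
              NULL
            })
        }
        for (m in methods) {
          i_rec <- i_rec + 1L
          rec_dgp[i_rec] <- dgp; rec_si[i_rec] <- si
          rec_sigma[i_rec] <- sigma; rec_rep[i_rec] <- r
          rec_method[i_rec] <- m
          if (m == "stepwise") {
            sel <- tryCatch(stepwise_select(ds, alpha = alpha)$selected,
                            error = function(e) {
                              message("stepwise failed (dgp ", dgp,
                                      ", rep ", r, "): ",
                                      conditionMessage(e))
                              NULL
                            })
            rec_ok[i_rec] <- !is.null(sel)
            rec_sel[[i_rec]] <- sel
          } else {
            thr <- if (m == "bma50") 0.5 else 0.95
            rec_ok[i_rec] <- !is.null(pip)
            rec_sel[[i_rec]] <- if (is.null(pip)) NULL else
              which(as.numeric(pip) >= thr)
            rec_pip[[i_rec]] <- if (is.null(pip)) NULL else as.numeric(pip)
          }
          if (!rec_ok[i_rec]) n_failed <- n_failed + 1L
        }
      }
    }
  }
  records <- data.frame(dgp = rec_dgp, sigma_index = rec_si,
                        sigma = rec_sigma, rep = rec_rep,
                        method = rec_method, ok = rec_ok)
  records$selected <- rec_sel
  records$pip <- rec_pip
  datasets <- data.frame(dgp = ds_dgp, sigma_index = ds_si, sigma = ds_sigma,
                         rep = ds_rep, seed = ds_seed,
                         t_x1 = ds_t1, t_x2 = ds_t2)
  structure(
    list(records = records, datasets = datasets, grid = grid,
         dgps = dgps, sigma_indices = sigma_indices, methods = methods,
         params = list(alpha = alpha, C = C, strict = strict, nbest = nbest,
                       exhaustive = exhaustive, n_reps = n_reps),
         n_failed = n_failed),
    class = "selection_experiment")
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat("Selection experiment:", nrow(x$datasets), "datasets x",
      length(x$methods), "methods (", nrow(x$records), "records,",
      x$n_failed, "failed )\n")
  invisible(x)
}

# variable roles for one DGP: list(true, redundant (uncorrelated),
# correlated_redundant, indirect)
.dgp_roles <- function(dgp, n_vars) {
  spec <- make_dgp_spec(dgp, n_vars)
  special <- c(spec$correlated_redundant, spec$indirect_predictor)
  list(true = spec$true_set,
       redundant = setdiff(seq_len(n_vars), c(spec$true_set, special)),
       correlated_redundant = spec$correlated_redundant,
       indirect = spec$indirect_predictor)
}

#' Estimate selection probabilities from experiment records
#'
#' Per (DGP, sigma, method) cell, estimates:
#' * `true_selected` — proportion of (replicate, true variable) pairs where
#'   the true predictor was selected (pooled over true predictors; for the
#'   two-predictor DGP the per-variable rows `true_selected_x1` /
#'   `true_selected_x2` are also emitted);
#' * `redundant_not_selected` — proportion of (replicate, redundant
#'   variable) pairs not selected, averaged over the redundant variables
#'   that are *uncorrelated* with a true predictor (the per-variable
#'   reading: under the null DGP stepwise selects each redundant variable
#'   with probability around its nominal level, not "any of the 20");
#' * `correlated_redundant_not_selected` — DGP 4's `x2` only;
#' * `indirect_selected` — DGP 5's `x2` only;
#' * `correct_model` — proportion of replicates whose selected set equals
#'   the true set exactly.
#'
#' Every estimate carries its binomial standard error
#' `sqrt(p(1-p)/m)` and the trial count `m`. Failed records are excluded
#' from denominators.
#'
#' @param experiment a [run_experiment()] result
#' @return data.frame (class `selection_probabilities`) with columns
#'   `dgp`, `sigma_index`, `sigma`, `method`, `metric`, `estimate`, `se`, `n`
#' @export
estimate_selection_probabilities <- function(experiment) {
  stopifnot(inherits(experiment, "selection_experiment"))
  rec <- experiment$records
  p <- experiment$grid$n_vars
  out <- list()
  cells <- unique(rec[, c("dgp", "sigma_index", "sigma", "method")])
  add <- function(dgp, si, sigma, method, metric, hits, m) {
    if (m == 0) return(NULL)  # empty cell: flagged missing by absence
    est <- hits / m
    data.frame(dgp = dgp, sigma_index = si, sigma = sigma, method = method,
               metric = metric, estimate = est,
               se = sqrt(est * (1 - est) / m), n = m)
  }
  for (i in seq_len(nrow(cells))) {
    dgp <- cells$dgp[i]; si <- cells$sigma_index[i]
    sigma <- cells$sigma[i]; method <- cells$method[i]
    idx <- which(rec$dgp == dgp & rec$sigma_index == si &
                   rec$method == method & rec$ok)
    if (!length(idx)) next
    sels <- rec$selected[idx]
    m <- length(idx)
    roles <- .dgp_roles(dgp, p)
    sel_mat <- matrix(FALSE, m, p)
    for (j in seq_len(m)) sel_mat[j, sels[[j]]] <- TRUE
    if (length(roles$true)) {
      hits <- sum(sel_mat[, roles$true, drop = FALSE])
      out[[length(out) + 1]] <- add(dgp, si, sigma, method, "true_selected",
                                    hits, m * length(roles$true))
      if (length(roles$true) > 1) {
        for (v in roles$true) {
          out[[length(out) + 1]] <- add(dgp, si, sigma, method,
                                        paste0("true_selected_x", v),
                                        sum(sel_mat[, v]), m)
        }
      }
    }
    if (length(roles$redundant)) {
      not_sel <- sum(!sel_mat[, roles$redundant, drop = FALSE])
      out[[length(out) + 1]] <- add(dgp, si, sigma, method,
                                    "redundant_not_selected", not_sel,
                                    m * length(roles$redundant))
    }
    if (!is.null(roles$correlated_redundant)) {
      out[[length(out) + 1]] <- add(dgp, si, sigma, method,
                                    "correlated_redundant_not_selected",
                                    sum(!sel_mat[, roles$correlated_redundant]),
                                    m)
    }
    if (!is.null(roles$indirect)) {
      out[[length(out) + 1]] <- add(dgp, si, sigma, method,
                                    "indirect_selected",
                                    sum(sel_mat[, roles$indirect]), m)
    }
    correct <- vapply(seq_len(m), function(j) {
      setequal(which(sel_mat[j, ]), roles$true)
    }, logical(1))
    out[[length(out) + 1]] <- add(dgp, si, sigma, method, "correct_model",
                                  sum(correct), m)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("selection_probabilities", "data.frame")
  res
}

#' Empirical effect-size axis
#'
#' For each (DGP, sigma) cell with at least one true predictor, the mean
#' absolute t statistic of `x1` in the full 20-variable model across
#' replicates. This is the x-axis for the operating-characteristic curves;
#' it is computed empirically (rather than from the closed form
#' `sqrt(n) * sd_partial(x1) / sigma`) because the correlated constructions
#' of DGPs 4 and 5 inflate the standard error of `beta_1`.
#'
#' @param experiment a [run_experiment()] result
#' @return data.frame with `dgp`, `sigma_index`, `sigma`, `effect_size`
#'   (mean |t| of x1), `effect_size_x2` (DGP 3 only, else NA), `n_reps`
#' @export
compute_effect_size <- function(experiment) {
  stopifnot(inherits(experiment, "selection_experiment"))
  d <- experiment$datasets[!is.na(experiment$datasets$t_x1), , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(dgp = integer(0), sigma_index = integer(0),
                      sigma = numeric(0), effect_size = numeric(0),
                      effect_size_x2 = numeric(0), n_reps = integer(0)))
  }
  key <- interaction(d$dgp, d$sigma_index, drop = TRUE)
  agg <- lapply(split(d, key), function(g) {
    data.frame(dgp = g$dgp[1], sigma_index = g$sigma_index[1],
               sigma = g$sigma[1], effect_size = mean(g$t_x1),
               effect_size_x2 = if (all(is.na(g$t_x2))) NA_real_
                                else mean(g$t_x2, na.rm = TRUE),
               n_reps = nrow(g))
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$dgp, res$sigma_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export estimates, manifest and figures
#'
#' Writes, into `out_dir`:
#' * `estimates.csv` — the tidy probability table joined with the empirical
#'   effect-size axis (columns `dgp`, `sigma_index`, `sigma`, `effect_size`,
#'   `method`, `metric`, `estimate`, `se`, `n`);
#' * `manifest.json` — seed, grid, method parameters, failure count and
#'   package version;
#' * four PDF figures: probability of not selecting a redundant variable,
#'   of selecting a true predictor, of selecting the correct model (one
#'   panel per DGP, one curve per method), and the complexity comparison
#'   (one panel per method, one curve per DGP), each against the empirical
#'   effect size on a log scale.
#'
#' @param experiment a [run_experiment()] result
#' @param out_dir output directory (created if missing; must be writable)
#' @param estimates optionally, a precomputed
#'   [estimate_selection_probabilities()] table
#' @return invisibly, the named vector of files written
#' @export
export_results <- function(experiment, out_dir, estimates = NULL) {
  stopifnot(inherits(experiment, "selection_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  if (is.null(estimates)) {
    estimates <- estimate_selection_probabilities(experiment)
  }
  eff <- compute_effect_size(experiment)
  tab <- merge(estimates,
               eff[, c("dgp", "sigma_index", "effect_size")],
               by = c("dgp", "sigma_index"), all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$dgp, tab$sigma_index, tab$method, tab$metric),
             c("dgp", "sigma_index", "sigma", "effect_size", "method",
               "metric", "estimate", "se", "n")]
  csv <- file.path(out_dir, "estimates.csv")
  write.csv(tab, csv, row.names = FALSE)

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(base_seed = experiment$grid$base_seed,
         n_obs = experiment$grid$n_obs, n_vars = experiment$grid$n_vars,
         sigmas = experiment$grid$sigmas,
         sigma_indices = experiment$sigma_indices,
         dgps = experiment$dgps, methods = experiment$methods,
         params = experiment$params,
         n_datasets = nrow(experiment$datasets),
         n_records = nrow(experiment$records),
         n_failed = experiment$n_failed,
         package_version = as.character(utils::packageVersion("stepbma"))),
    manifest, auto_unbox = TRUE, digits = NA)

  figs <- c(redundant = "fig_redundant_not_selected.pdf",
            true = "fig_true_selected.pdf",
            correct = "fig_correct_model.pdf",
            complexity = "fig_complexity_comparison.pdf")
  figs <- vapply(figs, function(f) file.path(out_dir, f), character(1))
  .plot_metric(tab, c("redundant_not_selected",
                      "correlated_redundant_not_selected"),
               "P(redundant variable not selected)", figs[["redundant"]])
  .plot_metric(tab, c("true_selected", "indirect_selected"),
               "P(true predictor selected)", figs[["true"]])
  .plot_metric(tab, "correct_model", "P(exactly the correct model)",
               figs[["correct"]])
  .plot_complexity(tab, figs[["complexity"]])
  invisible(c(estimates = csv, manifest = manifest, figs))
}

# metric-vs-effect-size curves, one panel per DGP, one colour per method
.plot_metric <- function(tab, metrics, ylab, file) {
  d <- tab[tab$metric %in% metrics & !is.na(tab$effect_size), , drop = FALSE]
  if (nrow(d) == 0) return(invisible(NULL))
  gp <- ggplot2::ggplot(
    d, ggplot2::aes(x = effect_size, y = estimate,
                    colour = method, linetype = metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, estimate - se),
                   ymax = pmin(1, estimate + se)), width = 0) +
    ggplot2::facet_wrap(~dgp, labeller = ggplot2::label_both) +
    ggplot2::scale_x_log10() + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "effect size (mean |t| of x1, full model)", y = ylab) +
    ggplot2::theme_bw()
  ggplot2::ggsave(file, gp, width = 8, height = 6, device = grDevices::pdf)
  invisible(file)
}

# true-predictor curves, one panel per method, one colour per DGP
.plot_complexity <- function(tab, file) {
  d <- tab[tab$metric == "true_selected" & !is.na(tab$effect_size), ,
           drop = FALSE]
  if (nrow(d) == 0) return(invisible(NULL))
  d$dgp <- factor(d$dgp)
  gp <- ggplot2::ggplot(
    d, ggplot2::aes(x = effect_size, y = estimate,
                    colour = dgp)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_x_log10() + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "effect size (mean |t| of x1, full model)",
                  y = "P(true predictor selected)") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file, gp, width = 8, height = 4, device = grDevices::pdf)
  invisible(file)
}
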