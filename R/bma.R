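#' Search the model space for low-RSS predictor subsets
#'
#' Finds, for every model size, the `nbest` subsets with the lowest residual
#' sum of squares (equivalently the lowest BIC at that size). The intercept-
#' only model (size 0) is always included.
#'
#' By default the search is pruned with a provable bound derived from RSS
#' monotonicity under nesting: a model of size k satisfies
#' `BIC >= n log(RSS_full / n) + (k + 1) log(n)`, so any model that can
#' survive Occam's window with constant `C` (i.e. with
#' `BIC <= BIC_best + 2 log C`) has size at most
#' `floor((BIC_ub + 2 log C - n log(RSS_full / n)) / log(n)) - 1`, where
#' `BIC_ub` is an upper bound on the best BIC taken from the forward path.
#' Sizes beyond that cap are provably excluded from the averaging window and
#' are not enumerated. With `exhaustive = TRUE` (or an explicit `max_size`)
#' all sizes up to `max_size` are enumerated with no `nbest` truncation,
#' which serves as the oracle mode for small problems.
#'
#' @param dataset a `sim_dataset`
#' @param nbest models kept per size (default 150)
#' @param max_size largest model size to enumerate; `NULL` (default) applies
#'   the Occam bound above
#' @param exhaustive if `TRUE`, enumerate every subset of every size
#' @param C Occam's window constant used by the pruning bound (default 20)
#' @return object of class `bma_models`: data.frame with list-column `vars`
#'   (sorted integer indices), `size`, `rss` and `bic`, ordered by size then
#'   BIC; attributes `n`, `n_vars`, `max_size`
#' @export
search_model_space <- function(dataset, nbest = 150, max_size = NULL,
                               exhaustive = FALSE, C = 20) {
  stopifnot(nbest >= 1, C > 1)
  gm <- .dataset_gram(dataset)
  if (gm$p > 31) stop("model-space search supports at most 31 predictors")
  if (gm$yy <= 0) stop("outcome is constant")
  # full-model RSS; rejects a rank-deficient full design
  rss_full <- .full_rss(gm)
  if (exhaustive) {
    max_size <- gm$p
    nbest <- choose(gm$p, floor(gm$p / 2))
  } else if (is.null(max_size)) {
    if (rss_full <= 0) {
      max_size <- gm$p  # perfect full fit: bound unavailable
    } else {
      fw <- forward_rss_cpp(gm$G, gm$g, gm$yy)
      rss_path <- c(gm$yy, as.numeric(fw$rss))
      pos <- rss_path > 0
      bic_ub <- min(bic_from_rss(rss_path[pos], gm$n,
                                 seq_along(rss_path)[pos]))
      max_size <- floor((bic_ub + 2 * log(C) - gm$n * log(rss_full / gm$n)) /
                          log(gm$n)) - 1
      max_size <- max(0L, min(gm$p, max_size))
    }
  }
  res <- subset_search_cpp(gm$G, gm$g, gm$yy, as.integer(max_size),
                           as.integer(nbest))
  vars <- list()
  size <- integer(0)
  rss <- numeric(0)
  for (k in seq_along(res)) {
    subs <- res[[k]]$subsets
    keep <- is.finite(res[[k]]$rss) & res[[k]]$rss > 0
    if (!any(keep)) next
    vars <- c(vars, lapply(which(keep), function(r) as.integer(subs[r, ])))
    size <- c(size, rep.int(k - 1L, sum(keep)))
    rss <- c(rss, res[[k]]$rss[keep])
  }
  out <- data.frame(size = size, rss = rss,
                    bic = bic_from_rss(rss, gm$n, size + 1L))
  out$vars <- vars
  structure(out[, c("vars", "size", "rss", "bic")],
            class = c("bma_models", "data.frame"),
            n = gm$n, n_vars = gm$p, max_size = max_size)
}

# RSS of the full design; errors if the full Gram matrix is singular
.full_rss <- function(gm) {
  ch <- tryCatch(chol(gm$G), error = function(e) NULL)
  if (is.null(ch)) {
    stop("full design is rank deficient; remove collinear predictors")
  }
  b <- backsolve(ch, forwardsolve(t(ch), gm$g))
  max(0, gm$yy - sum(gm$g * b))
}

#' Posterior model probabilities from BIC weights
#'
#' Converts BIC values into posterior model probabilities under a uniform
#' model prior, using the BIC approximation to the integrated likelihood:
#' `p(M_k | D) = exp(-(BIC_k - BIC_min)/2) / sum_l exp(-(BIC_l - BIC_min)/2)`.
#' The shift by the minimum BIC is exact algebraically and prevents
#' underflow. The result is invariant to adding any constant to all BICs.
#'
#' @param models a `bma_models` data.frame (or any data.frame with columns
#'   `vars` and `bic`)
#' @return the input with a `posterior` column summing to 1, class
#'   `bma_posterior`, sorted by decreasing posterior
#' @export
posterior_model_probabilities <- function(models) {
  if (NROW(models) == 0) stop("empty model list")
  stopifnot(all(c("vars", "bic") %in% names(models)))
  w <- exp(-(models$bic - min(models$bic)) / 2)
  models$posterior <- w / sum(w)
  models <- models[order(-models$posterior, models$size), , drop = FALSE]
  class(models) <- unique(c("bma_posterior", class(models)))
  models
}

#' Occam's window
#'
#' Retains the models whose posterior probability is within a factor `C` of
#' the best model's and renormalizes the retained probabilities to sum to 1.
#' With `strict = TRUE` the second principle is also applied: a retained
#' model is additionally removed when some retained strict submodel has a
#' strictly higher posterior probability. The consensus in the model-
#' averaging literature is not to use the second principle, so `strict`
#' defaults to `FALSE` ("non-strict Occam's window").
#'
#' @param posteriors a `bma_posterior` data.frame
#' @param C window constant (> 1, default 20)
#' @param strict apply the dominated-supermodel exclusion (default `FALSE`)
#' @return the retained rows, posterior renormalized; attribute `C`
#' @export
occams_window <- function(posteriors, C = 20, strict = FALSE) {
  stopifnot(inherits(posteriors, "bma_posterior") || all(
    c("vars", "posterior") %in% names(posteriors)), C > 1)
  pmax_ <- max(posteriors$posterior)
  keep <- pmax_ / posteriors$posterior <= C
  out <- posteriors[keep, , drop = FALSE]
  if (strict && nrow(out) > 1) {
    dominated <- vapply(seq_len(nrow(out)), function(i) {
      vi <- out$vars[[i]]
      pi_ <- out$posterior[i]
      any(vapply(seq_len(nrow(out)), function(j) {
        vj <- out$vars[[j]]
        length(vj) < length(vi) && all(vj %in% vi) && out$posterior[j] > pi_
      }, logical(1)))
    }, logical(1))
    out <- out[!dominated, , drop = FALSE]
  }
  out$posterior <- out$posterior / sum(out$posterior)
  attr(out, "C") <- C
  attr(out, "strict") <- strict
  out
}

#' Posterior inclusion probabilities
#'
#' For each variable, the sum of the posterior probabilities of the retained
#' models that contain it — the model-averaged posterior probability that
#' the variable belongs in the model.
#'
#' @param retained a renormalized `bma_posterior` (after [occams_window()])
#' @param n_vars total number of candidate variables
#' @return named numeric vector (`x1..xP`) of probabilities in `[0, 1]`
#' @export
inclusion_probabilities <- function(retained, n_vars) {
  stopifnot(all(c("vars", "posterior") %in% names(retained)), n_vars >= 1)
  tot <- sum(retained$posterior)
  if (abs(tot - 1) > 1e-6) {
    stop("retained posterior probabilities must sum to 1 (got ", tot,
         "); renormalize with occams_window() first")
  }
  pip <- numeric(n_vars)
  for (i in seq_len(NROW(retained))) {
    v <- retained$vars[[i]]
    pip[v] <- pip[v] + retained$posterior[i]
  }
  names(pip) <- paste0("x", seq_len(n_vars))
  pmin(pip, 1)
}

#' Bayesian model averaging selection
#'
#' The full BMA pipeline: model-space search, BIC-approximated posterior
#' model probabilities under a uniform prior, Occam's window (constant
#' `C = 20`, non-strict by default), posterior inclusion probabilities, and
#' thresholding. A variable is selected when its posterior inclusion
#' probability is **at or above** `threshold` (comparison operator `>=`;
#' conventional thresholds are 0.5 and 0.95). If the intercept-only model
#' dominates, every inclusion probability can fall below the threshold and
#' the empty set is returned.
#'
#' @param dataset a `sim_dataset`
#' @param threshold inclusion-probability cutoff in (0, 1), default 0.5
#' @param C Occam's window constant (default 20)
#' @param strict strict Occam's window (default `FALSE`)
#' @param nbest models kept per size during the search (default 150)
#' @param exhaustive exhaustive search (oracle mode; feasible for small p)
#' @return object of class `bma_selection`: list with `selected` (sorted
#'   indices), `pip` (named inclusion-probability vector), `threshold`,
#'   `retained` (windowed model table), `n_searched`, `method`
#' @examples
#' ds <- simulate_dataset(make_dgp_spec(2), sigma = 1, seed = 5)
#' sel <- bma_select(ds, threshold = 0.5)
#' sel$selected
#' round(sel$pip[1:5], 3)
#' @export
bma_select <- function(dataset, threshold = 0.5, C = 20, strict = FALSE,
                       nbest = 150, exhaustive = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  pip <- bma_inclusion(dataset, C = C, strict = strict, nbest = nbest,
                       exhaustive = exhaustive)
  structure(
    list(selected = which(pip >= threshold), pip = pip,
         threshold = threshold,
         retained = attr(pip, "retained"),
         n_searched = attr(pip, "n_searched"),
         method = if (threshold == 0.95) "bma95"
                  else if (threshold == 0.5) "bma50" else "bma"),
    class = "bma_selection")
}

#' @rdname bma_select
#' @details [bma_inclusion()] runs the pipeline once and returns only the
#'   inclusion probabilities (with the retained model table as an
#'   attribute); [bma_select()] thresholds them. When both the 50% and the
#'   95% rules are wanted on the same dataset, compute the probabilities
#'   once and threshold twice.
#' @export
bma_inclusion <- function(dataset, C = 20, strict = FALSE, nbest = 150,
                          exhaustive = FALSE) {
  models <- search_model_space(dataset, nbest = nbest,
                               exhaustive = exhaustive, C = C)
  post <- posterior_model_probabilities(models)
  ret <- occams_window(post, C = C, strict = strict)
  pip <- inclusion_probabilities(ret, attr(models, "n_vars"))
  attr(pip, "retained") <- ret
  attr(pip, "n_searched") <- nrow(models)
  pip
}

#' @export
print.bma_selection <- function(x, ...) {
  cat("BMA selection (threshold ", x$threshold, ", ",
      nrow(x$retained), " models in Occam's window):\n", sep = "")
  cat("  selected: ",
      if (length(x$selected)) paste0("x", x$selected, collapse = ", ")
      else "(empty)", "\n", sep = "")
  top <- sort(x$pip, decreasing = TRUE)
  top <- top[top > 0.01]
  if (length(top)) {
    cat("  inclusion probabilities > 0.01:\n")
    print(round(utils::head(top, 10), 4))
  }
  invisible(x)
}
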