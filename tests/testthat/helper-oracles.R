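# Independent oracles and toy-problem builders shared across test files.
# The oracles deliberately use a different computational route from the
# package: stats::lm / stats::step and plain-R enumeration over combn().

# a small dataset with iid N(0,1) predictors and y = X beta + N(0, sigma^2)
make_toy <- function(n, p, beta = numeric(p), sigma = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X %*% beta + rnorm(n, 0, sigma))
  as_sim_dataset(X, y)
}

# exhaustive BMA in plain R: all 2^p subsets fitted with lm(), BIC from the
# profile-likelihood formula, Occam's window by direct ratio test
r_exhaustive_bma <- function(dataset, C = 20, strict = FALSE) {
  X <- dataset$X
  y <- dataset$y
  n <- length(y)
  p <- ncol(X)
  subsets <- list(integer(0))
  for (k in 1:p) {
    subsets <- c(subsets, unlist(apply(combn(p, k), 2, list),
                                 recursive = FALSE))
  }
  bics <- vapply(subsets, function(S) {
    fit <- if (length(S)) lm(y ~ X[, S, drop = FALSE]) else lm(y ~ 1)
    rss <- sum(residuals(fit)^2)
    n * log(rss / n) + (length(S) + 1) * log(n)
  }, numeric(1))
  w <- exp(-(bics - min(bics)) / 2)
  post <- w / sum(w)
  keep <- max(post) / post <= C
  if (strict) {
    for (i in which(keep)) {
      vi <- subsets[[i]]
      for (j in which(keep)) {
        vj <- subsets[[j]]
        if (length(vj) < length(vi) && all(vj %in% vi) &&
            post[j] > post[i]) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  post <- post[keep] / sum(post[keep])
  subsets <- subsets[keep]
  pip <- numeric(p)
  for (i in seq_along(subsets)) pip[subsets[[i]]] <- pip[subsets[[i]]] + post[i]
  pip
}

# forward-AIC path via stats::step (same AIC constant as extractAIC)
r_forward_step <- function(dataset) {
  df <- data.frame(y = dataset$y, dataset$X)
  null_fit <- lm(y ~ 1, data = df)
  scope <- formula(lm(y ~ ., data = df))
  fit <- step(null_fit, scope = scope, direction = "forward", trace = 0)
  nm <- names(coef(fit))[-1]
  sort(as.integer(sub("^x", "", nm)))
}

# the paper-style composite: forward step then simultaneous p >= alpha prune
r_stepwise_oracle <- function(dataset, alpha = 0.05) {
  df <- data.frame(y = dataset$y, dataset$X)
  null_fit <- lm(y ~ 1, data = df)
  scope <- formula(lm(y ~ ., data = df))
  fit <- step(null_fit, scope = scope, direction = "forward", trace = 0)
  cf <- summary(fit)$coefficients
  if (nrow(cf) == 1) return(integer(0))
  keep <- rownames(cf)[-1][cf[-1, 4] < alpha]
  sort(as.integer(sub("^x", "", keep)))
}
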