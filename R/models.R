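#' Radial basis function kernel
#'
#' `k(x, y) = exp(-gamma * ||x - y||^2)` with the kernel scale
#' `gamma = 1 / (2 * sigma^2)`. Equal inputs give exactly 1; the value
#' decays monotonically with distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel scale, > 0.
#' @return Similarity in (0, 1].
#' @examples
#' rbf_kernel(0, 1, gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) {
    stop_seizr("'x' and 'y' must have equal dimensionality",
               "seizr_error_invalid_argument")
  }
  if (!is.numeric(gamma) || gamma <= 0) {
    stop_seizr("'gamma' must be > 0", "seizr_error_invalid_argument")
  }
  exp(-gamma * sum((x - y)^2))
}

#' RBF kernel matrix between row sets
#' @param X,Y Numeric matrices with matching column counts (`Y` defaults to
#'   `X`).
#' @inheritParams rbf_kernel
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
rbf_kernel_matrix <- function(X, Y = X, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop_seizr("'X' and 'Y' must have equal dimensionality",
               "seizr_error_invalid_argument")
  }
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' SVM configuration
#'
#' @param C Box constraint (soft-margin penalty weight), > 0.
#' @param kernel_scale RBF kernel scale gamma = 1 / (2 sigma^2), > 0; the
#'   default `NULL` uses 1 / n_features at fit time (the libsvm
#'   convention).
#' @param standardize Z-score the features with training statistics before
#'   fitting (default `TRUE`; without it kernel-scale values are not
#'   comparable across feature sets).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C = 1, kernel_scale = NULL, standardize = TRUE) {
  if (!is.numeric(C) || !is.finite(C) || C <= 0 ||
      (!is.null(kernel_scale) &&
       (!is.numeric(kernel_scale) || !is.finite(kernel_scale) ||
        kernel_scale <= 0))) {
    stop_seizr("'C' and 'kernel_scale' must be finite and positive",
               "seizr_error_invalid_argument")
  }
  structure(list(C = C, kernel_scale = kernel_scale,
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

feature_matrix <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) %in% c("channel_id", "label")] <- FALSE
  m <- as.matrix(table[, num, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit a multiclass RBF-SVM
#'
#' One-vs-one pairwise soft-margin SVMs with majority-vote prediction
#' (libsvm via e1071). Features are z-scored with the training rows'
#' statistics inside this function so the kernel scale acts on
#' standardized coordinates; prediction re-applies the stored statistics.
#' Pairwise voting ties are resolved by libsvm's fixed class order (the
#' order of first appearance in training data).
#'
#' @param table Feature table (`channel_id`, `label`, numeric feature
#'   columns) with >= 2 classes and >= 2 rows per class.
#' @param cfg An [svm_config()].
#' @return An object of class `seizr_svm`.
#' @export
svm_fit <- function(table, cfg = svm_config()) {
  y <- factor(table$label)
  if (nlevels(y) < 2) {
    stop_seizr("need at least 2 classes to fit an SVM",
               "seizr_error_invalid_argument")
  }
  if (any(table(y) < 2)) {
    stop_seizr("each class needs at least 2 training rows",
               "seizr_error_invalid_argument")
  }
  X <- feature_matrix(table)
  if (!all(is.finite(X))) {
    stop_seizr("non-finite feature values", "seizr_error_data")
  }
  if (cfg$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  gam <- cfg$kernel_scale %||% (1 / ncol(X))
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "radial", cost = cfg$C,
                    gamma = gam, scale = FALSE)
  structure(list(fit = fit, cfg = cfg, center = ctr, scale = scl,
                 features = colnames(X), levels = levels(y)),
            class = "seizr_svm")
}

#' Predict labels with a fitted SVM
#'
#' @param model A `seizr_svm` from [svm_fit()].
#' @param table Feature table (or bare numeric matrix) whose feature
#'   columns match the training columns.
#' @return Character vector of predicted labels, one per row.
#' @export
svm_predict <- function(model, table) {
  if (!inherits(model, "seizr_svm")) {
    stop_seizr("'model' must come from svm_fit()",
               "seizr_error_invalid_argument")
  }
  X <- if (is.matrix(table)) table else feature_matrix(table)
  if (!setequal(colnames(X), model$features) ||
      ncol(X) != length(model$features)) {
    stop_seizr("feature columns do not match the fitted model",
               "seizr_error_invalid_argument")
  }
  X <- X[, model$features, drop = FALSE]
  X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.character(stats::predict(model$fit, X))
}

# --------------------------------------------------------------------------
# Gaussian-process surrogate (Matern 5/2, profiled variance) and expected
# improvement, used to tune (C, gamma) on a log10 scale.

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

gp_corr <- function(U1, U2, ls) {
  d2 <- matrix(0, nrow(U1), nrow(U2))
  for (d in seq_len(ncol(U1))) {
    d2 <- d2 + outer(U1[, d], U2[, d], "-")^2 / ls[d]^2
  }
  matern52(sqrt(d2))
}

gp_fit <- function(U, y, jitter = 1e-10) {
  n <- length(y)
  ymu <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd <= 0) ysd <- 1
  ys <- (y - ymu) / ysd
  nll <- function(logls) {
    ls <- exp(logls)
    R <- gp_corr(U, U, ls) + diag(jitter + 1e-8, n)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    s2 <- sum(ys * alpha) / n
    if (s2 <= 0) return(1e10)
    n / 2 * log(s2) + sum(log(diag(ch)))
  }
  opt <- stats::optim(rep(log(0.3), ncol(U)), nll, method = "L-BFGS-B",
                      lower = log(0.03), upper = log(10))
  ls <- exp(opt$par)
  R <- gp_corr(U, U, ls) + diag(jitter + 1e-8, n)
  ch <- chol(R)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  s2 <- sum(ys * alpha) / n
  list(U = U, ls = ls, chol = ch, alpha = alpha, s2 = s2, ymu = ymu,
       ysd = ysd)
}

gp_predict <- function(fit, Unew) {
  Ks <- gp_corr(Unew, fit$U, fit$ls)
  mu <- drop(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  s2 <- pmax(fit$s2 * (1 - colSums(v^2)), 0)
  list(mean = fit$ymu + fit$ysd * mu,
       sd = fit$ysd * sqrt(fit$s2) * sqrt(pmax(1 - colSums(v^2), 0)))
}

expected_improvement <- function(mu, sd, best, xi = 0.01) {
  imp <- best - mu - xi
  z <- ifelse(sd > 0, imp / sd, 0)
  ei <- ifelse(sd > 0, imp * stats::pnorm(z) + sd * stats::dnorm(z),
               pmax(imp, 0))
  ei
}

#' Bayesian optimization of SVM hyperparameters
#'
#' Minimizes `objective(C, gamma)` over a log10-scaled box with a
#' Gaussian-process surrogate (Matern 5/2, fitted length scales) and the
#' expected-improvement acquisition. The initial design is the centre of
#' the box (C = 1, gamma = 1 under the default bounds — the package's
#' default SVM configuration) plus `n_init - 1` maximin Latin-hypercube
#' points; each later iteration maximizes EI over a fresh random candidate
#' set (ties broken by lowest candidate index). Non-finite objective
#' values are recorded as failures and imputed at the worst finite value
#' for the surrogate.
#'
#' @param objective Function of `(C, gamma)` returning a scalar to
#'   minimize, e.g. a cross-validated misclassification rate.
#' @param lower,upper Positive bounds for `c(C, gamma)`; default
#'   `[1e-3, 1e3]` on both axes.
#' @param budget Total objective evaluations (default 30).
#' @param n_init Initial design size (default 5), <= `budget`.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param n_candidates EI candidate-set size per iteration.
#' @param xi EI exploration margin.
#' @param init_points Optional matrix (or vector) of extra `(C, gamma)`
#'   warm-start points, evaluated before the space-filling design and
#'   counted against the budget — e.g. the current default configuration,
#'   which guarantees the incumbent never ends worse than it.
#' @return An object of class `bo_trace`: data frame `trace` with columns
#'   `iter, C, gamma, objective, incumbent` (incumbent objective is
#'   non-increasing), and `best` — list(C, gamma, objective).
#' @export
bayes_optimize <- function(objective, lower = c(1e-3, 1e-3),
                           upper = c(1e3, 1e3), budget = 30, n_init = 5,
                           seed = 1, n_candidates = 2000, xi = 0.01,
                           init_points = NULL) {
  if (any(lower <= 0) || any(upper <= lower)) {
    stop_seizr("bounds must be positive with upper > lower",
               "seizr_error_invalid_argument")
  }
  if (!is.null(init_points)) {
    init_points <- matrix(init_points, ncol = 2)
  }
  n_warm <- if (is.null(init_points)) 0L else nrow(init_points)
  if (budget < n_init + n_warm) {
    stop_seizr("'budget' must cover the initial design",
               "seizr_error_invalid_argument")
  }
  lo <- log10(lower); hi <- log10(upper)
  to_par <- function(u) 10^(lo + u * (hi - lo))
  to_u <- function(p) (log10(p) - lo) / (hi - lo)
  with_seed(seed, {
    U <- rbind(if (n_warm > 0) t(apply(init_points, 1, to_u)),
               matrix(0.5, 1, 2), lhs::maximinLHS(n_init - 1L, 2))
    evals <- numeric(0)
    for (i in seq_len(nrow(U))) {
      p <- to_par(U[i, ])
      evals[i] <- tryCatch(objective(p[1], p[2]), error = function(e)
        NA_real_)
    }
    while (length(evals) < budget) {
      y <- evals
      if (all(!is.finite(y))) y[] <- 0 else
        y[!is.finite(y)] <- max(y[is.finite(y)])
      fit <- gp_fit(U, y)
      cand <- matrix(stats::runif(n_candidates * 2), ncol = 2)
      pr <- gp_predict(fit, cand)
      best <- min(y)
      ei <- expected_improvement(pr$mean, pr$sd, best, xi)
      u_next <- cand[which.max(ei), , drop = FALSE]
      p <- to_par(drop(u_next))
      val <- tryCatch(objective(p[1], p[2]), error = function(e) NA_real_)
      U <- rbind(U, u_next)
      evals <- c(evals, val)
    }
    P <- t(apply(U, 1, to_par))
    obj <- evals
    inc <- cummin(ifelse(is.finite(obj), obj, Inf))
    trace <- data.frame(iter = seq_along(obj), C = P[, 1], gamma = P[, 2],
                        objective = obj, incumbent = inc)
    ibest <- which(is.finite(obj) & obj == min(obj[is.finite(obj)]))[1]
    structure(list(trace = trace,
                   best = list(C = P[ibest, 1], gamma = P[ibest, 2],
                               objective = obj[ibest]),
                   budget = budget, seed = seed),
              class = "bo_trace")
  })
}

#' Tune SVM hyperparameters by Bayesian optimization of CV error
#'
#' Convenience wrapper tying [bayes_optimize()] to
#' [cross_validated_report()]: the objective is the pooled k-fold
#' misclassification rate on `table` with fixed folds, and the search is
#' warm-started at the default configuration (C = 1, gamma = 1/n_features)
#' so the tuned model can never end worse than the default on those folds.
#'
#' @param table Balanced feature table.
#' @param k Folds for the inner CV (default 10).
#' @param cv_seed Seed fixing the fold assignment.
#' @param ... Passed to [bayes_optimize()] (`budget`, `seed`, bounds, ...).
#' @return List with `trace` (a `bo_trace`), `best_cfg` (an
#'   [svm_config()]), and `default_objective` (the warm-start value).
#' @export
tune_svm <- function(table, k = 10, cv_seed = 1, ...) {
  n_feat <- ncol(feature_matrix(table))
  objective <- function(C, gamma) {
    1 - cross_validated_report(table, svm_config(C, gamma), k = k,
                               seed = cv_seed)$metrics$overall_accuracy
  }
  default_pt <- c(1, 1 / n_feat)
  trace <- bayes_optimize(objective, init_points = default_pt, ...)
  list(trace = trace,
       best_cfg = svm_config(trace$best$C, trace$best$gamma),
       default_objective = trace$trace$objective[1])
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf(
    "<bo_trace> %d evaluations; best objective %.5g at C = %.4g, gamma = %.4g\n",
    nrow(x$trace), x$best$objective, x$best$C, x$best$gamma))
  invisible(x)
}
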