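#' Hyperparameter grid for the regularized logistic models
#'
#' Penalty type (L1 vs L2), regularization constant and iteration cap.  The
#' fitted models use exact penalized maximum likelihood (coordinate
#' descent), so no learning-rate schedule is tuned.
#'
#' @param penalty character subset of `c("l1", "l2")`.
#' @param lambda positive regularization constants.
#' @param maxit iteration caps.
#' @return data.frame of all combinations (class `hyperparameter_grid`).
#' @export
hyperparameter_grid <- function(penalty = c("l1", "l2"),
                                lambda = 10^seq(-5, -1, length.out = 5),
                                maxit = c(1e3, 1e4)) {
  stopifnot(length(penalty) > 0, all(lambda > 0), length(lambda) > 0)
  g <- expand.grid(penalty = penalty, lambda = lambda, maxit = maxit,
                   stringsAsFactors = FALSE)
  class(g) <- c("hyperparameter_grid", "data.frame")
  g
}

as_binary_labels <- function(labels) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  y
}

# inverse-class-frequency ("balanced") observation weights
balanced_weights <- function(y) {
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  w
}

#' Train a class-weighted regularized logistic regression
#'
#' Binary cross-entropy objective with per-observation weights inversely
#' proportional to class frequency, and an L1 or L2 penalty, fitted by
#' glmnet at a single fixed regularization constant.
#'
#' @param features numeric matrix (complete; at least two columns).
#' @param labels 0/1 vector.
#' @param hyperparams list with `penalty` (`"l1"`/`"l2"`), `lambda`,
#'   `maxit`.
#' @param seed integer (kept for interface symmetry; the fit is
#'   deterministic).
#' @return an `ogttda_logreg` object with elements `fit`, `hyperparams`,
#'   `feature_names`, and `coefficients` (named vector incl. intercept).
#' @export
train_logreg <- function(features, labels,
                         hyperparams = list(penalty = "l2", lambda = 0.01,
                                            maxit = 1e4),
                         seed = 1L) {
  y <- as_binary_labels(labels)
  x <- as.matrix(features)
  stopifnot(ncol(x) >= 2, nrow(x) == length(y), !anyNA(x))
  alpha <- switch(hyperparams$penalty, l1 = 1, l2 = 0,
                  stop("penalty must be 'l1' or 'l2'"))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = hyperparams$lambda,
                        weights = balanced_weights(y),
                        standardize = FALSE,
                        maxit = as.integer(hyperparams$maxit))
  co <- as.numeric(stats::coef(fit, s = hyperparams$lambda))
  names(co) <- rownames(stats::coef(fit))
  structure(list(fit = fit, hyperparams = hyperparams,
                 feature_names = colnames(x), coefficients = co),
            class = "ogttda_logreg")
}

#' Predicted IGM probabilities
#'
#' @param object an `ogttda_logreg` model.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.ogttda_logreg <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, as.matrix(newdata),
                            s = object$hyperparams$lambda,
                            type = "response"))
}

# Stratified fold assignment: class proportions per fold within +/- 1.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split with train size exactly round(frac * n).
stratified_split <- function(y, frac, seed) {
  set.seed(seed)
  n_train <- round(frac * length(y))
  pos <- sample(which(y == 1))
  neg <- sample(which(y == 0))
  n_pos_train <- min(round(frac * length(pos)), n_train)
  train <- c(pos[seq_len(n_pos_train)],
             neg[seq_len(n_train - n_pos_train)])
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

weighted_bce <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Tune hyperparameters by stratified k-fold cross-validation
#'
#' Selects the grid point with minimum mean validation binary
#' cross-entropy over stratified folds.  Deterministic given `seed`.
#'
#' @param features,labels training data.
#' @param grid a [hyperparameter_grid()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `best` (one-row config), `losses` (per-grid-point mean
#'   validation loss).
#' @export
tune_hyperparameters <- function(features, labels, grid = hyperparameter_grid(),
                                 k = 5, seed = 1L) {
  y <- as_binary_labels(labels)
  stopifnot(k >= 2)
  if (min(table(y)) < k) {
    stop("a stratified fold would lack one class; use smaller k")
  }
  fold <- stratified_folds(y, k, seed)
  x <- as.matrix(features)
  losses <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- list(penalty = grid$penalty[g], lambda = grid$lambda[g],
               maxit = grid$maxit[g])
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- train_logreg(x[tr, , drop = FALSE], y[tr], hp)
      weighted_bce(y[!tr], predict(m, x[!tr, , drop = FALSE]))
    }, 0))
  }, 0)
  list(best = grid[which.min(losses), , drop = FALSE], losses = losses)
}

#' Repeated stratified 70--30 split protocol
#'
#' Performs `n_splits` independent seeded stratified train/test splits,
#' tunes hyperparameters within each train set, records the held-out
#' metrics, and reports the modal selected configuration.
#'
#' @param features,labels the cohort data (`n >= 30`).
#' @param grid a [hyperparameter_grid()].
#' @param n_splits number of repetitions (default 30).
#' @param train_fraction train proportion (default 0.7).
#' @param k folds for the inner tuning loop.
#' @param seed master seed; per-split seeds are derived from it.
#' @return list with `selection` (modal best config), `splits` (per-split
#'   data.frame: penalty, lambda, maxit, test AUROC/AP), `mean_auroc`,
#'   `mean_ap`.
#' @export
repeated_split_protocol <- function(features, labels, grid = hyperparameter_grid(),
                                    n_splits = 30, train_fraction = 0.7,
                                    k = 5, seed = 1L) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) >= 30)
  x <- as.matrix(features)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_splits)
  rows <- lapply(seq_len(n_splits), function(s) {
    sp <- stratified_split(y, train_fraction, seeds[s])
    tuned <- tune_hyperparameters(x[sp$train, , drop = FALSE], y[sp$train],
                                  grid, k, seed = seeds[s])
    hp <- as.list(tuned$best)
    m <- train_logreg(x[sp$train, , drop = FALSE], y[sp$train], hp)
    p <- predict(m, x[sp$test, , drop = FALSE])
    data.frame(penalty = hp$penalty, lambda = hp$lambda, maxit = hp$maxit,
               auroc = auroc(p, y[sp$test]),
               ap = average_precision(p, y[sp$test]))
  })
  splits <- do.call(rbind, rows)
  key <- paste(splits$penalty, splits$lambda, splits$maxit)
  modal <- splits[match(names(sort(table(key), decreasing = TRUE))[1], key), 1:3]
  list(selection = modal, splits = splits,
       mean_auroc = mean(splits$auroc), mean_ap = mean(splits$ap))
}

#' Bootstrap out-of-bag evaluation
#'
#' Each replicate resamples the cohort with replacement, refits the model
#' on the in-bag patients (or rescores a fixed fit when `refit = FALSE`)
#' and scores the out-of-bag patients.  Replicates whose out-of-bag (or,
#' when refitting, in-bag) set contains a single class are skipped and
#' counted.  Metrics are averaged over replicates with percentile 95% CIs.
#'
#' @param features,labels the cohort data.
#' @param hyperparams model configuration passed to [train_logreg()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param refit refit per replicate (default TRUE); `FALSE` scores a single
#'   full-data fit (fast mode).
#' @param variant label carried into the report.
#' @param threshold probability cut for precision/recall (default 0.5).
#' @return an `evaluation_report`: list with `variant`, `metrics`
#'   (data.frame metric/mean/ci_lo/ci_hi), `replicates` (per-replicate
#'   metric data.frame), `coefficients` (mean over replicates, refit mode),
#'   `n_boot`, `n_skipped`, `seed`.
#' @export
bootstrap_oob_evaluate <- function(features, labels, hyperparams,
                                   n_boot = 1000, seed = 1L, refit = TRUE,
                                   variant = "model", threshold = 0.5) {
  y <- as_binary_labels(labels)
  x <- as.matrix(features)
  n <- length(y)
  set.seed(seed)
  base_model <- if (!refit) train_logreg(x, y, hyperparams) else NULL
  reps <- vector("list", n_boot)
  coefs <- NULL
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(unique(y[oob])) < 2 ||
        (refit && length(unique(y[idx])) < 2)) {
      n_skipped <- n_skipped + 1L
      next
    }
    m <- if (refit) train_logreg(x[idx, , drop = FALSE], y[idx], hyperparams)
         else base_model
    p <- predict(m, x[oob, , drop = FALSE])
    yo <- y[oob]
    pred <- p >= threshold
    tp <- sum(pred & yo == 1)
    reps[[b]] <- data.frame(
      auroc = auroc(p, yo),
      ap = average_precision(p, yo),
      precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
      recall = tp / sum(yo == 1)
    )
    if (refit) {
      coefs <- if (is.null(coefs)) m$coefficients
               else coefs + m$coefficients
    }
  }
  reps <- do.call(rbind, reps)
  if (n_skipped > 0.1 * n_boot) {
    warning(n_skipped, " of ", n_boot, " replicates skipped (single-class sets)")
  }
  metrics <- do.call(rbind, lapply(names(reps), function(m) {
    v <- reps[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               ci_lo = stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE),
               ci_hi = stats::quantile(v, 0.975, na.rm = TRUE, names = FALSE))
  }))
  structure(list(variant = variant, metrics = metrics, replicates = reps,
                 coefficients = if (!is.null(coefs)) coefs / nrow(reps),
                 n_boot = n_boot, n_skipped = n_skipped, seed = seed),
            class = "evaluation_report")
}

#' Area under the ROC curve
#'
#' Mann--Whitney probability that a random positive outranks a random
#' negative, with 0.5 credit for ties.
#'
#' @param scores predicted scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  r <- rank(scores)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' Prevalence-weighted summary of the precision--recall curve:
#' `AP = sum_i (R_i - R_{i-1}) P_i` over thresholds at each distinct score
#' in decreasing order.  Constant scores give AP equal to the positive
#' prevalence; perfect ranking gives 1.
#'
#' @inheritParams auroc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  y <- as_binary_labels(labels)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  cum_tp <- cumsum(ys)
  cum_pred <- seq_along(ys)
  # thresholds at the last index of each distinct score
  last <- which(c(ss[-length(ss)] != ss[-1], TRUE))
  prec <- cum_tp[last] / cum_pred[last]
  rec <- cum_tp[last] / sum(y == 1)
  sum(diff(c(0, rec)) * prec)
}

#' Compare two bootstrap evaluation reports
#'
#' Two-tailed t-tests on the per-replicate metric vectors of two variants,
#' with a configurable (Bonferroni-style) significance threshold.
#' Identical replicate vectors yield p = 1.
#'
#' @param report_a,report_b `evaluation_report` objects with equal
#'   replicate counts.
#' @param metrics which metrics to compare.
#' @param alpha significance threshold after multiplicity adjustment
#'   (default 0.004, matching a Bonferroni-corrected family).
#' @return data.frame: metric, mean_a, mean_b, diff, p_value, significant.
#' @export
compare_variants <- function(report_a, report_b,
                             metrics = c("auroc", "ap", "precision", "recall"),
                             alpha = 0.004) {
  if (nrow(report_a$replicates) != nrow(report_b$replicates)) {
    stop("replicate counts differ between reports")
  }
  do.call(rbind, lapply(metrics, function(m) {
    a <- report_a$replicates[[m]]
    b <- report_b$replicates[[m]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    p <- if (isTRUE(all.equal(a, b))) 1
         else if (stats::sd(a) == 0 && stats::sd(b) == 0)
           as.numeric(mean(a) == mean(b))
         else stats::t.test(a, b)$p.value
    data.frame(metric = m, mean_a = mean(a), mean_b = mean(b),
               diff = mean(a) - mean(b), p_value = p,
               significant = p < alpha)
  }))
}

#' Write an evaluation report to JSON (+ coefficient table)
#'
#' @param report an `evaluation_report`.
#' @param file JSON output path; coefficients (when present) go to
#'   `paste0(file, "_coefficients.csv")`.
#' @export
write_evaluation_report <- function(report, file) {
  jsonlite::write_json(
    list(variant = report$variant,
         metrics = report$metrics,
         n_boot = report$n_boot, n_skipped = report$n_skipped,
         seed = report$seed),
    file, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(report$coefficients)) {
    utils::write.csv(
      data.frame(term = names(report$coefficients),
                 estimate = as.numeric(report$coefficients)),
      paste0(file, "_coefficients.csv"), row.names = FALSE)
  }
}
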