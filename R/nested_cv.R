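# Nested cross-validation demonstration of the feature filter. The outer
# loop estimates performance on untouched test folds; the filter (including
# its percolation threshold) is fitted on the outer-training split only, and
# the inner loop tunes the classifier's regularization strength. The
# classifier is a deliberately simple, swappable elastic-net logistic model.

stratified_folds <- function(y, k) {
  idx <- integer(length(y))
  for (lev in levels(y)) {
    which_lev <- which(y == lev)
    if (length(which_lev) < k)
      stop_diffnetx(
        sprintf("class '%s' has %d samples, fewer than %d folds",
                lev, length(which_lev), k),
        "diffnetx_error_stratification")
    idx[which_lev] <- sample(rep_len(seq_len(k), length(which_lev)))
  }
  idx
}

binary_auc <- function(prob, y01) {
  as.numeric(pROC::auc(pROC::roc(response = y01, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# median-impute from training columns; classifiers cannot digest NA ratios
impute_from_train <- function(train, test) {
  med <- apply(train, 2, function(col) stats::median(col, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  fix <- function(m) {
    for (j in seq_len(ncol(m))) {
      bad <- !is.finite(m[, j])
      if (any(bad)) m[bad, j] <- med[j]
    }
    m
  }
  list(train = fix(train), test = fix(test))
}

tune_and_predict <- function(ztr, ytr, zte, inner_k) {
  if (ncol(ztr) == 0) return(rep(0.5, nrow(zte)))
  imp <- impute_from_train(ztr, zte)
  ztr <- imp$train; zte <- imp$test
  y01 <- as.numeric(ytr == levels(ytr)[2])
  if (ncol(ztr) >= 2 && min(table(ytr)) >= 3) {
    foldid <- stratified_folds(ytr, min(inner_k, min(table(ytr))))
    cv <- tryCatch(
      glmnet::cv.glmnet(ztr, y01, family = "binomial", foldid = foldid,
                        alpha = 0.5, nlambda = 50, standardize = TRUE),
      error = function(e) NULL)
    if (!is.null(cv))
      return(as.numeric(stats::predict(cv, zte, s = "lambda.min",
                                       type = "response")))
  }
  df <- data.frame(y = y01, ztr, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  newdf <- data.frame(zte, check.names = TRUE)
  as.numeric(suppressWarnings(stats::predict(fit, newdf, type = "response")))
}

#' Nested cross-validation demonstration of the edge filter
#'
#' Repeats a stratified `outer_k`-fold cross-validation `repeats` times. In
#' each outer fold the filter is fitted with [fit_filter()] on the training
#' split only, both splits are transformed with [transform_features()], an
#' elastic-net logistic classifier is tuned by `inner_k`-fold inner
#' cross-validation, and predictions on the untouched outer test split are
#' pooled within the repeat to yield one AUC, accuracy and balanced accuracy
#' per repeat.
#'
#' @param x Samples x features numeric matrix.
#' @param y Two-level group vector (named or in `rownames(x)` order).
#' @param net A [reference_network()].
#' @param outer_k,inner_k Outer / inner fold counts (defaults 5 and 10).
#' @param repeats Number of repeats of the whole procedure (default 16).
#' @param seed Optional integer seed; the same seed reproduces fold
#'   assignments and metrics exactly.
#' @param max_features,keep_single Passed to [fit_filter()].
#' @param ... Further arguments for [fit_filter()] /
#'   [percolation_scan()].
#' @return Data frame with one row per repeat: `repeat_id`, `auc`,
#'   `accuracy`, `balanced_accuracy`, `mean_n_features`.
#' @export
nested_cv_demo <- function(x, y, net, outer_k = 5, inner_k = 10,
                           repeats = 16, seed = NULL, max_features = Inf,
                           keep_single = TRUE, ...) {
  x <- as.matrix(x)
  yv <- as.character(y)
  if (!is.null(names(yv))) yv <- yv[rownames(x)]
  yf <- factor(yv)
  if (nlevels(yf) != 2)
    stop_diffnetx("two-class outcome required",
                  "diffnetx_error_too_few_groups")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(yf, outer_k)
    prob <- rep(NA_real_, nrow(x))
    nfeat <- numeric(outer_k)
    for (fold in seq_len(outer_k)) {
      tr <- folds != fold
      model <- fit_filter(x[tr, , drop = FALSE], yv[tr], net,
                          max_features = max_features,
                          keep_single = keep_single, ...)
      ztr <- transform_features(model, x[tr, , drop = FALSE])
      zte <- transform_features(model, x[!tr, , drop = FALSE])
      nfeat[fold] <- ncol(ztr)
      prob[!tr] <- tune_and_predict(ztr, yf[tr], zte, inner_k)
    }
    y01 <- as.numeric(yf == levels(yf)[2])
    pred <- as.numeric(prob >= 0.5)
    sens <- mean(pred[y01 == 1] == 1)
    spec <- mean(pred[y01 == 0] == 0)
    out[[r]] <- data.frame(repeat_id = r,
                           auc = binary_auc(prob, y01),
                           accuracy = mean(pred == y01),
                           balanced_accuracy = (sens + spec) / 2,
                           mean_n_features = mean(nfeat))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
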