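#' MLP configuration
#'
#' A feed-forward network with exactly two sigmoid hidden layers and a
#' softmax output, trained by full-batch Adam on the cross-entropy loss
#' with early stopping: within every training set, 70% of the rows update
#' the weights and the remaining 30% define the stopping condition (best
#' validation loss, `patience` epochs of grace, best weights restored).
#' `hidden = "auto"` sizes the layers as `min(64, 4 * n_predictors)` and
#' half that (rounded up).
#'
#' @param hidden `"auto"` or integer vector of 2 layer sizes.
#' @param stop_fraction validation share of each training set, in (0,1).
#' @param max_epochs,patience training schedule.
#' @param learning_rate Adam step size.
#' @param seed integer seed for fold assignment and weight initialization.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = "auto", stop_fraction = 0.30,
                       max_epochs = 500, patience = 20,
                       learning_rate = 0.05, seed = 1L) {
  if (!identical(hidden, "auto")) {
    if (length(hidden) != 2 || any(hidden < 1))
      stop_invalid("hidden must be 'auto' or 2 positive sizes")
    hidden <- as.integer(hidden)
  }
  if (stop_fraction <= 0 || stop_fraction >= 1)
    stop_invalid("stop_fraction must be in (0, 1)")
  structure(list(hidden = hidden, stop_fraction = stop_fraction,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Train a 2-hidden-layer sigmoid MLP with softmax output by full-batch
# Adam; early stopping on (xv, yv). y matrices are one-hot.
mlp_train <- function(x, y, xv, yv, hidden, config) {
  p <- ncol(x); k <- ncol(y)
  h1 <- hidden[1]; h2 <- hidden[2]
  glorot <- function(nin, nout)
    matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  W <- list(glorot(p, h1), glorot(h1, h2), glorot(h2, k))
  b <- list(numeric(h1), numeric(h2), numeric(k))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  forward <- function(W, b, x) {
    a1 <- sigmoid(sweep(x %*% W[[1]], 2, b[[1]], `+`))
    a2 <- sigmoid(sweep(a1 %*% W[[2]], 2, b[[2]], `+`))
    out <- softmax_rows(sweep(a2 %*% W[[3]], 2, b[[3]], `+`))
    list(a1 = a1, a2 = a2, out = out)
  }
  xent <- function(pr, y) -mean(rowSums(y * log(pmax(pr, 1e-12))))
  best <- list(loss = Inf, W = W, b = b)
  wait <- 0; t <- 0
  for (epoch in seq_len(config$max_epochs)) {
    f <- forward(W, b, x)
    d3 <- (f$out - y) / n                       # softmax + cross-entropy
    d2 <- (d3 %*% t(W[[3]])) * f$a2 * (1 - f$a2)
    d1 <- (d2 %*% t(W[[2]])) * f$a1 * (1 - f$a1)
    gW <- list(crossprod(x, d1), crossprod(f$a1, d2), crossprod(f$a2, d3))
    gb <- list(colSums(d1), colSums(d2), colSums(d3))
    t <- t + 1
    for (l in 1:3) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t)) /
        (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) /
        (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
    }
    vloss <- xent(forward(W, b, xv)$out, yv)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, W = W, b = b)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  list(W = best$W, b = best$b, forward = forward, epochs = epoch)
}

mlp_predict_prob <- function(model, x)
  model$forward(model$W, model$b, as.matrix(x))$out

#' Tenfold cross-validation of the CO2-free MLP classifier
#'
#' Splits the labelled feature table at random into 10 equal folds
#' (unstratified, seeded). For each fold: standardization (center/scale)
#' is fit on the training portion only and applied to the held-out fold;
#' an inner 70/30 split drives early stopping; accuracy and per-class
#' sensitivity (recall) and precision are computed on the held-out fold.
#' ROC curves use the pooling strategy: held-out class scores are
#' concatenated across folds and a single ROC/AUC per class is computed
#' on the pool.
#'
#' @param features data.frame with predictor columns and a `cycle_type`
#'   column.
#' @param predictors character vector of predictor names; must not contain
#'   `insp_co2_volume` (the classifier is CO2-free by contract).
#' @param config an [mlp_config()].
#' @param folds number of folds.
#' @return An object of class `cv_result`: `per_fold` data.frame
#'   (accuracy per fold), `accuracy` (min/mean/max, %), `sensitivity` and
#'   `precision` (min/mean/max per class, %), `auc` data.frame per class
#'   with Hanley-McNeil 95% CI, and the pooled `scores`.
#' @export
run_cv <- function(features, predictors = co2_free_predictors(),
                   config = mlp_config(), folds = 10) {
  if ("insp_co2_volume" %in% predictors)
    stop_invalid("predictor list must exclude insp_co2_volume: ",
                 "the classifier is CO2-free by contract")
  missing <- setdiff(predictors, names(features))
  if (length(missing))
    stop_invalid("predictors absent from table: ",
                 paste(missing, collapse = ", "))
  y <- factor(features$cycle_type)
  if (nlevels(y) < 2)
    stop_invalid("need >= 2 classes in cycle_type (got ",
                 nlevels(y), "): cannot train a classifier")
  classes <- levels(y)
  x <- as.matrix(features[, predictors])
  storage.mode(x) <- "double"
  n <- nrow(x)
  set.seed(config$seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  onehot <- function(f) {
    m <- matrix(0, length(f), length(classes))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  acc <- numeric(folds)
  sens <- matrix(NA, folds, length(classes), dimnames = list(NULL, classes))
  prec <- matrix(NA, folds, length(classes), dimnames = list(NULL, classes))
  pooled <- vector("list", folds)
  hid <- config$hidden
  if (identical(hid, "auto")) {
    h1 <- min(64L, 4L * length(predictors))
    hid <- c(h1, as.integer(ceiling(h1 / 2)))
  }
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xs_tr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
    xs_te <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, `/`)
    y_tr <- y[tr]; y_te <- y[te]
    set.seed(config$seed + f)
    n_tr <- nrow(xs_tr)
    val <- sample(n_tr, max(1, round(config$stop_fraction * n_tr)))
    model <- mlp_train(xs_tr[-val, , drop = FALSE], onehot(y_tr[-val]),
                       xs_tr[val, , drop = FALSE], onehot(y_tr[val]),
                       hid, config)
    pr <- mlp_predict_prob(model, xs_te)
    colnames(pr) <- classes
    pred <- factor(classes[max.col(pr)], levels = classes)
    acc[f] <- mean(pred == y_te)
    for (j in seq_along(classes)) {
      pos <- y_te == classes[j]
      if (any(pos)) sens[f, j] <- mean(pred[pos] == classes[j])
      if (any(pred == classes[j]))
        prec[f, j] <- mean(y_te[pred == classes[j]] == classes[j])
    }
    pooled[[f]] <- data.frame(fold = f, truth = as.character(y_te), pr,
                              check.names = FALSE)
  }
  pooled <- do.call(rbind, pooled)
  auc <- do.call(rbind, lapply(classes, function(cl) {
    r <- pooled_roc(pooled[[cl]], pooled$truth == cl)
    data.frame(class = cl, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2])
  }))
  mmm <- function(v) c(min = min(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE),
                       max = max(v, na.rm = TRUE)) * 100
  structure(list(per_fold = data.frame(fold = seq_len(folds),
                                       accuracy = 100 * acc),
                 accuracy = mmm(acc),
                 sensitivity = apply(sens, 2, mmm),
                 precision = apply(prec, 2, mmm),
                 auc = auc, scores = pooled,
                 predictors = predictors, hidden = hid),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("MLP %d-fold CV: accuracy %.1f%% (min %.1f, max %.1f)\n",
              nrow(x$per_fold), x$accuracy["mean"], x$accuracy["min"],
              x$accuracy["max"]))
  print(x$auc, row.names = FALSE)
  invisible(x)
}

#' Pooled ROC AUC with Hanley-McNeil confidence interval
#'
#' Empirical one-vs-rest AUC on pooled held-out scores, computed by the
#' Mann-Whitney rank statistic (identical to the trapezoidal area under
#' the empirical ROC curve, with ties counted half). The 95% CI uses the
#' Hanley-McNeil standard-error formula.
#'
#' @param scores numeric vector of class scores.
#' @param positive logical vector marking the positive class.
#' @param conf confidence level.
#' @return list: `auc`, `ci` (length-2 vector), `se`, `n_pos`, `n_neg`.
#' @export
pooled_roc <- function(scores, positive, conf = 0.95) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop_invalid("AUC undefined: need both positive and negative labels")
  r <- rank(scores)
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ci = pmin(1, pmax(0, c(auc - z * se, auc + z * se))),
       se = se, n_pos = n1, n_neg = n0)
}
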