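#' One-way fixed-effects ANOVA for one feature
#'
#' Classical one-way F test of equality of the per-type means (equal
#' variances assumed, as in the standard fixed-effects decomposition).
#'
#' @param values numeric vector.
#' @param group factor/character of the same length (>= 2 groups, each with
#'   >= 2 observations).
#' @return list: `feature` (attribute name if any), `F`, `p`, and a
#'   data.frame `groups` with n, mean, sd per group.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop_invalid("need >= 2 groups")
  ns <- tapply(values, group, length)
  if (any(is.na(ns)) || any(ns < 2))
    stop_invalid("every group needs >= 2 observations")
  gm <- tapply(values, group, mean)
  if (max(gm) - min(gm) == 0 && var(values) == 0) {
    f <- 0; p <- 1
  } else {
    ow <- oneway.test(values ~ group, var.equal = TRUE)
    f <- unname(ow$statistic); p <- unname(ow$p.value)
    if (!is.finite(f)) { f <- 0; p <- 1 }
  }
  list(F = f, p = p,
       groups = data.frame(group = levels(group), n = as.integer(ns),
                           mean = as.numeric(gm),
                           sd = as.numeric(tapply(values, group, sd))))
}

#' Newman-Keuls stepwise pairwise comparisons
#'
#' Stepwise multiple comparison of ordered group means using studentized
#' range critical values whose stretch parameter shrinks with the span of
#' each comparison. The pooled error is the ANOVA mean square within;
#' unbalanced groups use the harmonic-mean n (classical balanced formula).
#' A pair inside a stretch already declared non-significant is not tested
#' (declared non-significant), as the stepwise procedure requires.
#'
#' @param values numeric vector.
#' @param group factor/character grouping.
#' @param alpha significance level.
#' @return data.frame with one row per pair: `group1`, `group2`, `q`
#'   (studentized range statistic), `stretch`, `critical`, `significant`.
#' @export
snk_pairwise <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop_invalid("need >= 2 groups")
  ns <- tapply(values, group, length)
  if (any(is.na(ns)) || any(ns < 2))
    stop_invalid("every group needs >= 2 observations")
  means <- tapply(values, group, mean)
  n_tot <- length(values)
  df_w <- n_tot - k
  mse <- sum((values - ave(values, group))^2) / df_w
  ord <- order(means)                      # ascending
  lev <- levels(group)[ord]; m <- as.numeric(means[ord])
  n_h <- k / sum(1 / ns)                   # harmonic mean group size
  se <- sqrt(mse / n_h)
  # test stretches from widest to narrowest; once a stretch is accepted
  # (non-significant), everything inside it is non-significant
  sig <- matrix(NA, k, k)
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      if (!is.na(sig[i, j])) next
      q <- if (se > 0) (m[j] - m[i]) / se else 0
      crit <- qtukey(1 - alpha, r, df_w)
      if (q > crit) {
        sig[i, j] <- TRUE
      } else {
        for (a in i:j) for (b in a:j) if (is.na(sig[a, b])) sig[a, b] <- FALSE
      }
    }
  }
  rows <- list(); idx <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    idx <- idx + 1
    r <- j - i + 1
    rows[[idx]] <- data.frame(
      group1 = lev[i], group2 = lev[j],
      q = if (se > 0) (m[j] - m[i]) / se else 0,
      stretch = r, critical = qtukey(1 - alpha, r, df_w),
      significant = isTRUE(sig[i, j]))
  }
  do.call(rbind, rows)
}

#' ANOVA + Newman-Keuls over a whole feature table
#'
#' @param features data.frame with feature columns and a `cycle_type`
#'   column.
#' @param vars feature columns to test (default: all 17).
#' @param alpha significance level for the pairwise tests.
#' @return data.frame with one row per feature: F, p and one
#'   significance flag per group pair.
#' @export
feature_anova_table <- function(features,
                                vars = setdiff(names(features),
                                               c("cycle", "cycle_type")),
                                alpha = 0.05) {
  lv <- levels(factor(features$cycle_type))
  rows <- lapply(vars, function(v) {
    a <- anova_oneway(features[[v]], features$cycle_type)
    snk <- snk_pairwise(features[[v]], features$cycle_type, alpha)
    # canonical pair naming (level order), stable across features
    i1 <- match(snk$group1, lv); i2 <- match(snk$group2, lv)
    nm <- paste0(lv[pmin(i1, i2)], "_vs_", lv[pmax(i1, i2)])
    flags <- setNames(snk$significant, nm)[order(nm)]
    cbind(data.frame(feature = v, F = a$F, p = a$p),
          as.data.frame(as.list(flags)))
  })
  do.call(rbind, rows)
}

#' Canonical discriminant analysis
#'
#' Canonical variates are the leading eigenvectors of the
#' within-class-inverse times between-class scatter matrix; with g classes
#' at most g-1 variates exist. Discriminative power is summarized by
#' Wilks' lambda = prod(1/(1+lambda_i)) over the retained eigenvalues.
#' Observations are classified by the nearest class centroid in canonical
#' space with equal priors, and the confusion matrix is computed by
#' resubstitution on the same data.
#'
#' @param x numeric matrix or data.frame of features.
#' @param labels class labels.
#' @param ridge optional ridge added to the within-class scatter (fraction
#'   of its mean diagonal) if it is singular; `NA` disables the fallback.
#' @return An object of class `cda_result`: canonical coefficients,
#'   eigenvalues, `wilks_lambda`, class `centroids`, `scores`,
#'   `confusion` matrix and `percent_correct` (from
#'   [confusion_summary()]).
#' @export
cda_fit <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- factor(labels)
  g <- nlevels(labels); p <- ncol(x); n <- nrow(x)
  if (g < 2) stop_invalid("need >= 2 classes")
  if (n != length(labels)) stop_invalid("x and labels disagree in length")
  grand <- colMeans(x)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  centers <- matrix(0, g, p)
  for (j in seq_len(g)) {
    xi <- x[labels == levels(labels)[j], , drop = FALSE]
    ci <- colMeans(xi)
    centers[j, ] <- ci
    xc <- sweep(xi, 2, ci)
    W <- W + crossprod(xc)
    B <- B + nrow(xi) * tcrossprod(ci - grand)
  }
  ridged <- FALSE
  Wi <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Wi)) {
    if (is.na(ridge)) stop_invalid("within-class scatter is singular")
    W <- W + ridge * mean(diag(W)) * diag(p)
    Wi <- solve(W)
    ridged <- TRUE
  }
  ev <- eigen(Wi %*% B)
  keep <- seq_len(min(g - 1, p))
  lambda <- Re(ev$values[keep])
  coefs <- Re(ev$vectors[, keep, drop = FALSE])
  # scale coefficients to unit pooled within-class variance of the scores
  for (j in seq_along(keep)) {
    s <- sqrt(drop(t(coefs[, j]) %*% W %*% coefs[, j]) / (n - g))
    if (s > 0) coefs[, j] <- coefs[, j] / s
  }
  rownames(coefs) <- colnames(x)
  colnames(coefs) <- paste0("CD", seq_along(keep))
  scores <- x %*% coefs
  centroids <- apply(scores, 2, function(s) tapply(s, labels, mean))
  centroids <- matrix(centroids, nrow = g,
                      dimnames = list(levels(labels), colnames(coefs)))
  d2 <- sapply(seq_len(g), function(j)
    rowSums(sweep(scores, 2, centroids[j, ])^2))
  pred <- factor(levels(labels)[max.col(-d2)], levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)
  structure(list(coefficients = coefs, eigenvalues = lambda,
                 wilks_lambda = prod(1 / (1 + lambda)),
                 centroids = centroids, scores = scores,
                 predicted = pred,
                 confusion = unclass(confusion),
                 percent_correct = confusion_summary(unclass(confusion)),
                 ridged = ridged),
            class = "cda_result")
}

#' @export
print.cda_result <- function(x, ...) {
  cat("Canonical discriminant analysis:", ncol(x$coefficients),
      "variates, Wilks' lambda =", signif(x$wilks_lambda, 4), "\n")
  cat("Resubstitution overall % correct:",
      x$percent_correct$overall, "\n")
  invisible(x)
}

#' Per-class and overall percent correct from a confusion matrix
#'
#' Rows are true classes, columns predictions. Per-class percent correct
#' is diagonal / row total x 100 (two decimals); overall is
#' trace / total x 100.
#'
#' @param m square nonnegative count matrix.
#' @return list: `per_class` named vector, `overall`, `column_totals`.
#' @export
confusion_summary <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_invalid("confusion matrix must be square")
  if (any(m < 0)) stop_invalid("counts must be nonnegative")
  rt <- rowSums(m)
  if (any(rt == 0)) stop_invalid("zero row total in confusion matrix")
  per <- round(100 * diag(m) / rt, 2)
  overall <- round(100 * sum(diag(m)) / sum(m), 2)
  list(per_class = per, overall = overall, column_totals = colSums(m))
}
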