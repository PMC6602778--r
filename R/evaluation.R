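# Diagnostic-accuracy evaluation: 2x2 tables, sensitivity/specificity/
# predictive values/likelihood ratios with 95% CIs, LOOCV, a 7-scheme
# k-fold battery, out-of-bag bootstrap, and a Fisher exact test by
# hypergeometric enumeration.

#' Build a 2x2 contingency table (IBS = positive class)
#'
#' Either pass the four counts directly or truth/predicted label vectors.
#'
#' @param TP,FN,FP,TN non-negative counts.
#' @param truth,pred label vectors (used when counts are missing).
#' @param positive positive-class label.
#' @return object of class `contingency_table` with fields `TP,FN,FP,TN`.
#' @export
contingency_table <- function(TP = NULL, FN = NULL, FP = NULL, TN = NULL,
                              truth = NULL, pred = NULL, positive = "IBS") {
  if (is.null(TP)) {
    stopifnot(length(truth) == length(pred))
    t_pos <- truth == positive
    p_pos <- pred == positive
    TP <- sum(t_pos & p_pos); FN <- sum(t_pos & !p_pos)
    FP <- sum(!t_pos & p_pos); TN <- sum(!t_pos & !p_pos)
  }
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  structure(as.list(counts), class = "contingency_table")
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# Log-method CI for a likelihood ratio built from a 2x2 table.
lr_ci <- function(lr, a, m, b, n, conf = 0.95) {
  # lr = (a/m) / (b/n); SE(log lr) = sqrt(1/a - 1/m + 1/b - 1/n)
  if (!is.finite(lr) || lr <= 0 || a == 0 || b == 0)
    return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a - 1 / m + 1 / b - 1 / n)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic accuracy metrics with 95% confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy with Wilson score
#' intervals; positive and negative likelihood ratios with log-method
#' intervals. Division by zero yields `Inf` with an undefined (NA) interval.
#'
#' @param table a [contingency_table()].
#' @param conf confidence level (default 0.95).
#' @return object of class `diagnostic_metrics`: a data frame with one row
#'   per metric (`estimate`, `ci_low`, `ci_high`), plus the table as an
#'   attribute.
#' @export
diagnostic_metrics <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  TP <- table$TP; FN <- table$FN; FP <- table$FP; TN <- table$TN
  n_pos <- TP + FN; n_neg <- TN + FP; n <- n_pos + n_neg
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("invalid table: each class needs at least one participant")
  sens <- TP / n_pos
  spec <- TN / n_neg
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  npv <- if (TN + FN > 0) TN / (TN + FN) else NA_real_
  acc <- (TP + TN) / n
  lr_pos <- if (spec < 1) sens / (1 - spec) else if (sens > 0) Inf else NaN
  lr_neg <- if (spec > 0) (1 - sens) / spec else NaN
  rows <- rbind(
    data.frame(metric = "sensitivity", estimate = sens,
               t(wilson_ci(TP, n_pos, conf))),
    data.frame(metric = "specificity", estimate = spec,
               t(wilson_ci(TN, n_neg, conf))),
    data.frame(metric = "ppv", estimate = ppv,
               t(wilson_ci(TP, TP + FP, conf))),
    data.frame(metric = "npv", estimate = npv,
               t(wilson_ci(TN, TN + FN, conf))),
    data.frame(metric = "accuracy", estimate = acc,
               t(wilson_ci(TP + TN, n, conf))),
    data.frame(metric = "lr_pos", estimate = lr_pos,
               t(lr_ci(lr_pos, TP, n_pos, FP, n_neg, conf))),
    data.frame(metric = "lr_neg", estimate = lr_neg,
               t(lr_ci(lr_neg, FN, n_pos, TN, n_neg, conf))))
  names(rows)[3:4] <- c("ci_low", "ci_high")
  rownames(rows) <- NULL
  structure(rows, class = c("diagnostic_metrics", "data.frame"),
            table = table)
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  tab <- attr(x, "table")
  cat(sprintf("2x2 table: TP=%d FN=%d FP=%d TN=%d\n",
              tab$TP, tab$FN, tab$FP, tab$TN))
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 3)
  df$ci_low <- signif(df$ci_low, 3)
  df$ci_high <- signif(df$ci_high, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out cross-validation of the acoustic-index classifier
#'
#' Each fold holds out one participant; imputation, standardisation, the
#' optional feature selection and the logistic fit are redone on the
#' remaining participants. Deterministic.
#'
#' @param x feature matrix with row-identifying names and column names.
#' @param y labels (positive class `"IBS"`).
#' @param lambda ridge penalty.
#' @param select if `TRUE`, rerun [select_features()] inside every training
#'   fold (honest but expensive).
#' @param positive positive-class label.
#' @return list with `table` ([contingency_table()]), `predictions` (data
#'   frame: `index`, `truth`, `pred`) and `accuracy`.
#' @export
loocv <- function(x, y, lambda = 1, select = FALSE, positive = "IBS") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop_invalid("LOOCV needs at least 3 participants")
  as_binary_labels(y, positive)   # validates both classes present
  idx <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2) { idx[i] <- NA; next }
    feats <- colnames(x)
    if (select)
      feats <- select_features(xtr, ytr, lambda, positive = positive)$selected
    m <- fit_logistic(xtr[, feats, drop = FALSE], ytr, lambda, positive)
    idx[i] <- ibs_acoustic_index(m, x[i, feats, drop = FALSE])
  }
  pred <- ifelse(idx >= 0.5, positive, "healthy")
  # a fold whose training set lost a class is flagged and counted as an error
  pred[is.na(idx)] <- ifelse(y[is.na(idx)] == positive, "healthy", positive)
  list(table = contingency_table(truth = y, pred = pred, positive = positive),
       predictions = data.frame(index = idx, truth = as.character(y),
                                pred = pred, stringsAsFactors = FALSE),
       accuracy = mean(pred == y))
}

# Deterministic fold assignment; identity order when seed is NULL.
make_folds <- function(y, k, stratified, seed, positive = "IBS") {
  n <- length(y)
  ord <- seq_len(n)
  if (!is.null(seed)) ord <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  if (stratified) {
    # continuous round-robin across classes: per-class and total fold
    # sizes both stay within one of each other
    counter <- 0L
    for (cls in unique(as.character(y))) {
      members <- ord[as.character(y)[ord] == cls]
      folds[members] <- (counter + seq_along(members) - 1L) %% k + 1L
      counter <- counter + length(members)
    }
  } else {
    folds[ord] <- rep_len(seq_len(k), n)
  }
  folds
}

#' k-fold cross-validation
#'
#' Folds differ in size by at most one; the stratified variant balances the
#' class ratio across folds. With `k = n` and no seed this is exactly LOOCV.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param k number of folds, `2 <= k <= n`.
#' @param stratified preserve class ratios per fold.
#' @param seed optional integer; when given, participants are shuffled
#'   reproducibly before assignment.
#' @param lambda ridge penalty.
#' @param positive positive-class label.
#' @return as [loocv()], plus `folds`.
#' @export
kfold_cv <- function(x, y, k, stratified = FALSE, seed = NULL, lambda = 1,
                     positive = "IBS") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2 || k > n) stop_invalid("k must be in [2, n]")
  folds <- make_folds(y, k, stratified, seed, positive)
  idx <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (!length(te) || length(unique(y[tr])) < 2) next
    m <- fit_logistic(x[tr, , drop = FALSE], y[tr], lambda, positive)
    idx[te] <- ibs_acoustic_index(m, x[te, , drop = FALSE])
  }
  pred <- ifelse(idx >= 0.5, positive, "healthy")
  ok <- !is.na(idx)
  list(table = contingency_table(truth = y[ok], pred = pred[ok],
                                 positive = positive),
       predictions = data.frame(index = idx, truth = as.character(y),
                                pred = pred, stringsAsFactors = FALSE),
       accuracy = mean(pred[ok] == y[ok]), folds = folds)
}

#' The default battery of 7 cross-validation schemes
#'
#' k in {2, 5, 10}, each stratified and unstratified, plus leave-one-out
#' (k = n): seven schemes in total.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param seed integer seed for fold shuffling.
#' @param lambda ridge penalty.
#' @return data frame with one row per scheme (`scheme`, `accuracy`,
#'   `sensitivity`, `specificity`).
#' @export
cv_battery <- function(x, y, seed = 1L, lambda = 1) {
  schemes <- list()
  for (k in c(2, 5, 10)) for (s in c(TRUE, FALSE))
    schemes[[sprintf("k%d_%s", k, if (s) "stratified" else "plain")]] <-
      kfold_cv(x, y, k, stratified = s, seed = seed, lambda = lambda)
  schemes[["loocv"]] <- loocv(x, y, lambda = lambda)
  do.call(rbind, lapply(names(schemes), function(nm) {
    dm <- diagnostic_metrics(schemes[[nm]]$table)
    data.frame(scheme = nm,
               accuracy = dm$estimate[dm$metric == "accuracy"],
               sensitivity = dm$estimate[dm$metric == "sensitivity"],
               specificity = dm$estimate[dm$metric == "specificity"])
  }))
}

#' Out-of-bag bootstrap evaluation
#'
#' `B` stratified resamples with replacement serve as training sets; each
#' model is evaluated on its out-of-bag participants. Counts are pooled into
#' one 2x2 table; per-replicate accuracies give percentile intervals. A
#' resample whose out-of-bag set is empty is redrawn (logged).
#'
#' @param x feature matrix.
#' @param y labels.
#' @param B number of bootstrap repetitions (default 300).
#' @param seed integer seed.
#' @param lambda ridge penalty.
#' @param positive positive-class label.
#' @return list with `metrics` (pooled [diagnostic_metrics()]), `table`,
#'   `accuracy_ci` (2.5/97.5 percentiles of per-replicate accuracy),
#'   `replicates` (per-replicate accuracy), `B`, `n_redraws`.
#' @export
bootstrap_eval <- function(x, y, B = 300L, seed = 1L, lambda = 1,
                           positive = "IBS") {
  if (B < 1) stop_invalid("B must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  pos_i <- which(y == positive)
  neg_i <- which(y != positive)
  with_seed(seed, {
    counts <- c(TP = 0L, FN = 0L, FP = 0L, TN = 0L)
    acc <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        tr <- c(sample(pos_i, length(pos_i), replace = TRUE),
                sample(neg_i, length(neg_i), replace = TRUE))
        oob <- setdiff(seq_len(n), tr)
        if (length(oob) && length(unique(y[tr])) == 2) break
        redraws <- redraws + 1L
      }
      m <- fit_logistic(x[tr, , drop = FALSE], y[tr], lambda, positive)
      pred <- ifelse(ibs_acoustic_index(m, x[oob, , drop = FALSE]) >= 0.5,
                     positive, "healthy")
      tt <- y[oob] == positive
      counts <- counts + c(TP = sum(tt & pred == positive),
                           FN = sum(tt & pred != positive),
                           FP = sum(!tt & pred == positive),
                           TN = sum(!tt & pred != positive))
      acc[b] <- mean(pred == y[oob])
    }
    tab <- contingency_table(counts["TP"], counts["FN"], counts["FP"],
                             counts["TN"])
    list(metrics = diagnostic_metrics(tab), table = tab,
         accuracy = mean(acc),
         accuracy_ci = stats::quantile(acc, c(0.025, 0.975), names = FALSE),
         replicates = acc, B = B, n_redraws = redraws)
  })
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' probabilities of those no more probable than the observed table.
#'
#' @param table 2x2 matrix of non-negative counts (e.g. correct/incorrect by
#'   subgroup).
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2) || any(m < 0) || any(m != round(m)))
    stop_invalid("need a 2x2 matrix of non-negative integer counts")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (N == 0) return(1)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
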