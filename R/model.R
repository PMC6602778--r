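# L2-penalised logistic regression, the IBS Acoustic Index, and greedy
# forward feature selection driven by LOOCV accuracy.
#
# The fit is plain iteratively reweighted least squares with a ridge penalty
# on standardised features (intercept unpenalised); with n = 68 participants
# and 26 features an unpenalised fit would separate, so the default penalty
# is 1.0. Standardisation, median imputation and (optionally) selection are
# always refit inside each cross-validation training fold - no leakage.

as_binary_labels <- function(y, positive = "IBS") {
  yv <- as.character(y)
  u <- unique(yv)
  if (length(u) < 2) stop_invalid("degenerate labels: only one class present")
  if (length(u) > 2) stop_invalid("labels must be binary")
  as.integer(yv == positive)
}

#' Fit an L2-penalised logistic regression
#'
#' Maximises the penalised log-likelihood
#' `sum(y log p + (1-y) log(1-p)) - lambda/2 * ||beta||^2` by Newton/IRLS on
#' standardised features, to gradient tolerance 1e-8. Missing values are
#' imputed with per-feature training medians; zero-variance features are
#' dropped (and recorded). Deterministic.
#'
#' @param x numeric feature matrix (rows = participants) with column names.
#' @param y labels; the positive class is `"IBS"`.
#' @param lambda ridge penalty on standardised coefficients (default 1).
#' @param positive positive-class label.
#' @param max_iter,tol IRLS iteration cap and gradient tolerance.
#' @return object of class `ibs_model`: feature names, imputation medians,
#'   standardisation means/SDs, intercept, coefficients, `lambda`, dropped
#'   features.
#' @export
fit_logistic <- function(x, y, lambda = 1, positive = "IBS",
                         max_iter = 200L, tol = 1e-8) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  yb <- as_binary_labels(y, positive)
  if (nrow(x) != length(yb)) stop_invalid("x and y sizes differ")
  if (nrow(x) < 2) stop_invalid("need at least 2 observations")
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  dropped <- colnames(x)[!keep]
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  p <- ncol(xs)
  beta <- numeric(p); b0 <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(b0 + xs %*% beta)
    pr <- stats::plogis(eta)
    g0 <- sum(yb - pr)
    g <- drop(crossprod(xs, yb - pr)) - lambda * beta
    if (max(abs(c(g0, g))) < tol) break
    w <- pmax(pr * (1 - pr), 1e-10)
    Xa <- cbind(1, xs)
    H <- crossprod(Xa * sqrt(w))
    if (p) H[-1, -1] <- H[-1, -1] + diag(lambda, p)
    step <- solve(H, c(g0, g))
    b0 <- b0 + step[1]
    if (p) beta <- beta + step[-1]
  }
  structure(list(
    feature_names = colnames(x), kept = colnames(x)[keep],
    dropped = dropped, medians = med,
    center = mu[keep], scale = sdv[keep],
    intercept = b0, coefficients = stats::setNames(beta, colnames(x)[keep]),
    lambda = lambda, positive = positive, iterations = it),
    class = "ibs_model")
}

#' IBS Acoustic Index of new participants
#'
#' The index is the logistic of the standardised linear predictor, a value in
#' `[0, 1]` interpreted as the probability of IBS. Values of 0.5 and above
#' predict IBS (the boundary is inclusive); values below 0.5 predict healthy.
#' There are no indeterminate results.
#'
#' @param model an `ibs_model` from [fit_logistic()].
#' @param x feature matrix or single named feature vector; column names must
#'   cover the model's features.
#' @return numeric vector of indices in `[0, 1]`.
#' @export
ibs_acoustic_index <- function(model, x) {
  stopifnot(inherits(model, "ibs_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!all(model$feature_names %in% colnames(x)))
    stop_invalid("feature names do not match the model (missing: %s)",
                 paste(setdiff(model$feature_names, colnames(x)),
                       collapse = ", "))
  x <- x[, model$kept, drop = FALSE]
  for (j in seq_len(ncol(x)))
    x[!is.finite(x[, j]), j] <- model$medians[[colnames(x)[j]]]
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  unname(stats::plogis(model$intercept + drop(xs %*% model$coefficients)))
}

#' Predicted class labels from the acoustic index
#' @param model an `ibs_model`.
#' @param x feature matrix or named vector.
#' @return character vector, `"IBS"` (index >= 0.5) or `"healthy"`.
#' @export
predict_label <- function(model, x) {
  idx <- ibs_acoustic_index(model, x)
  ifelse(idx >= 0.5, model$positive, "healthy")
}

# LOOCV accuracy of a feature subset (used by the selector); the full
# per-fold pipeline (imputation, standardisation, fit) is rerun each fold.
loocv_accuracy <- function(x, y, lambda, positive = "IBS") {
  yb <- as_binary_labels(y, positive)
  n <- nrow(x)
  correct <- logical(n)
  for (i in seq_len(n)) {
    if (length(unique(yb[-i])) < 2) next
    m <- fit_logistic(x[-i, , drop = FALSE], y[-i], lambda, positive)
    correct[i] <- (ibs_acoustic_index(m, x[i, , drop = FALSE]) >= 0.5) ==
      (yb[i] == 1L)
  }
  mean(correct)
}

#' Greedy forward feature selection by LOOCV accuracy
#'
#' Starting from the empty set, repeatedly adds the feature whose inclusion
#' maximises leave-one-out accuracy; stops when accuracy has failed to
#' improve on the best value for `plateau` consecutive additions (or when
#' all features are in). Returns the subset at the accuracy plateau and the
#' full trace. When selection is part of an honest evaluation it must be
#' rerun inside each outer training fold (see `select` in [loocv()]).
#'
#' @param x feature matrix with column names.
#' @param y labels.
#' @param lambda ridge penalty passed to [fit_logistic()].
#' @param plateau number of consecutive non-improving additions tolerated.
#' @param positive positive-class label.
#' @return list with `selected` (character), `trace` (data frame of step,
#'   feature, accuracy, improved).
#' @export
select_features <- function(x, y, lambda = 1, plateau = 3,
                            positive = "IBS") {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_invalid("need at least 2 candidate features")
  remaining <- colnames(x)
  chosen <- character(0)
  best_acc <- -Inf
  best_set <- character(0)
  stale <- 0L
  trace <- list()
  step <- 0L
  while (length(remaining) && stale < plateau) {
    step <- step + 1L
    accs <- vapply(remaining, function(f)
      loocv_accuracy(x[, c(chosen, f), drop = FALSE], y, lambda, positive),
      numeric(1))
    add <- remaining[which.max(accs)]
    acc <- max(accs)
    chosen <- c(chosen, add)
    remaining <- setdiff(remaining, add)
    improved <- acc > best_acc
    if (improved) {
      best_acc <- acc
      best_set <- chosen
      stale <- 0L
    } else stale <- stale + 1L
    trace[[step]] <- data.frame(step = step, feature = add, accuracy = acc,
                                improved = improved)
  }
  list(selected = best_set,
       trace = do.call(rbind, trace))
}

#' Serialise / restore a fitted model
#'
#' Human-readable JSON holding feature names, imputation medians,
#' standardisation parameters, intercept, coefficients and the penalty.
#'
#' @param model an `ibs_model`.
#' @param path file path.
#' @return `read_model` returns the restored `ibs_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ibs_model"))
  obj <- unclass(model)
  for (f in c("medians", "center", "scale", "coefficients"))
    obj[[f]] <- as.list(obj[[f]])   # keep names: serialise as JSON objects
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("medians", "center", "scale", "coefficients"))
    obj[[f]] <- unlist(obj[[f]])
  obj$dropped <- as.character(obj$dropped)
  structure(obj, class = "ibs_model")
}
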