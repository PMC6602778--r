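# Random-intercept linear mixed model for the fed/fasted repeated-measures
# design, fitted by maximum likelihood with the variance ratio profiled out.
#
# Model: y_ij = x_ij' beta + b_i + e_ij, b_i ~ N(0, sigma_b^2),
# e_ij ~ N(0, sigma_e^2). For a given ratio r = sigma_b^2 / sigma_e^2 the
# cluster covariance is sigma_e^2 (I + r J), whose inverse has the closed
# form (I - r/(1 + m r) J) / sigma_e^2 for a cluster of size m, so the GLS
# normal equations and sigma_e^2 are available in closed form and only the
# scalar r is optimised numerically. Each fixed effect is tested with a
# Wald chi-square on 1 df.

# Profiled log-likelihood machinery. X: n x p design, y: response,
# cluster: integer cluster index.
lmm_profile <- function(r, X, y, cluster) {
  p <- ncol(X)
  A <- matrix(0, p, p); bvec <- numeric(p)
  ldet <- 0; n <- length(y)
  for (ix in split(seq_len(n), cluster)) {
    m <- length(ix)
    Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
    w <- r / (1 + m * r)
    cx <- colSums(Xi); cy <- sum(yi)
    A <- A + crossprod(Xi) - w * tcrossprod(cx)
    bvec <- bvec + crossprod(Xi, yi) - w * cx * cy
    ldet <- ldet + log1p(m * r)
  }
  beta <- solve(A, bvec)
  rss <- 0
  for (ix in split(seq_len(n), cluster)) {
    m <- length(ix)
    res <- y[ix] - X[ix, , drop = FALSE] %*% beta
    w <- r / (1 + m * r)
    rss <- rss + sum(res^2) - w * sum(res)^2
  }
  sigma_e2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma_e2) + n + ldet)
  list(loglik = ll, beta = drop(beta), sigma_e2 = sigma_e2, A = A, r = r)
}

#' Fit a random-intercept linear mixed model by profiled ML
#'
#' For a two-period repeated-measures design: response modelled as
#' `response ~ group * period + (1 | participant)`. Estimation is maximum
#' likelihood: the variance ratio `r = sigma_b^2 / sigma_e^2` is profiled
#' and optimised on the log scale; fixed effects are then GLS estimates.
#' Each fixed-effect coefficient is tested with a Wald chi-square
#' (`(estimate/SE)^2`, df = 1) in the full model, an approximation to a
#' Type-II analysis.
#'
#' @param data data frame with columns `participant_id`, `group`
#'   (`healthy`/`IBS`), `period` (`fasted`/`fed`) and `response`, one row
#'   per participant-period.
#' @return object of class `bs_lmm`: `coefficients` (data frame with
#'   `estimate`, `se`, `chisq`, `p`), `sigma_b2`, `sigma_e2`, `ratio`,
#'   `loglik`, `n_obs`, `n_participants`.
#' @export
fit_random_intercept_lmm <- function(data) {
  need <- c("participant_id", "group", "period", "response")
  if (!all(need %in% names(data)))
    stop_invalid("data needs columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(data$response)))
    stop_invalid("non-finite responses")
  grp <- factor(data$group, levels = c("healthy", "IBS"))
  per <- factor(data$period, levels = c("fasted", "fed"))
  if (any(is.na(grp)) || any(is.na(per)))
    stop_invalid("group must be healthy/IBS and period fasted/fed")
  if (length(unique(data$participant_id[grp == "IBS"])) < 2 ||
      length(unique(data$participant_id[grp == "healthy"])) < 2)
    stop_invalid("need at least 2 participants per group")
  X <- stats::model.matrix(~ grp * per)
  colnames(X) <- c("(Intercept)", "groupIBS", "periodfed",
                   "groupIBS:periodfed")
  cluster <- as.integer(factor(data$participant_id))
  y <- data$response
  obj <- function(logr) lmm_profile(exp(logr), X, y, cluster)$loglik
  opt <- stats::optimize(obj, interval = c(-14, 14), maximum = TRUE,
                         tol = 1e-10)
  at_zero <- lmm_profile(0, X, y, cluster)
  best <- lmm_profile(exp(opt$maximum), X, y, cluster)
  if (at_zero$loglik >= best$loglik) best <- at_zero
  se <- sqrt(diag(solve(best$A)) * best$sigma_e2)
  est <- best$beta
  chisq <- (est / se)^2
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      chisq = chisq,
                      p = wald_chisq_pvalue(chisq, 1),
                      row.names = NULL)
  structure(list(coefficients = coefs,
                 sigma_b2 = best$r * best$sigma_e2,
                 sigma_e2 = best$sigma_e2,
                 ratio = best$r, loglik = best$loglik,
                 n_obs = length(y),
                 n_participants = length(unique(cluster))),
            class = "bs_lmm")
}

#' @export
print.bs_lmm <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (ML): %d obs, %d participants\n",
    x$n_obs, x$n_participants))
  cat(sprintf("sigma_b^2 = %.4g, sigma_e^2 = %.4g, logLik = %.3f\n",
              x$sigma_b2, x$sigma_e2, x$loglik))
  df <- x$coefficients
  df$estimate <- signif(df$estimate, 4); df$se <- signif(df$se, 4)
  df$chisq <- round(df$chisq, 2); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Upper-tail p-value of a Wald chi-square statistic
#'
#' @param chisq non-negative statistic(s).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @export
wald_chisq_pvalue <- function(chisq, df) {
  if (any(df < 1) || any(df != round(df)))
    stop_invalid("df must be a positive integer")
  if (any(chisq < 0)) stop_invalid("chisq must be non-negative")
  stats::pchisq(chisq, df, lower.tail = FALSE)
}

#' Simulate a repeated-measures cohort for the mixed model
#'
#' Generates one observation per participant and period from the
#' random-intercept model: response = intercept + ibs_effect * [IBS] +
#' food_effect * [fed] + interaction * [IBS & fed] + participant intercept +
#' noise.
#'
#' @param n_ibs,n_healthy participants per group.
#' @param intercept,ibs_effect,food_effect,interaction fixed effects.
#' @param sd_intercept random-intercept SD.
#' @param sd_resid residual SD.
#' @param seed integer seed.
#' @return long-format data frame (`participant_id`, `group`, `period`,
#'   `response`).
#' @export
simulate_lmm_cohort <- function(n_ibs = 50, n_healthy = 50, intercept = 1,
                                ibs_effect = -0.2, food_effect = 0.5,
                                interaction = 0, sd_intercept = 0.3,
                                sd_resid = 0.2, seed = 1L) {
  with_seed(seed, {
    n <- n_ibs + n_healthy
    ids <- sprintf("P%03d", seq_len(n))
    grp <- rep(c("IBS", "healthy"), c(n_ibs, n_healthy))
    b <- stats::rnorm(n, 0, sd_intercept)
    rows <- lapply(seq_len(n), function(i) {
      mu <- intercept + ibs_effect * (grp[i] == "IBS") +
        c(0, food_effect + interaction * (grp[i] == "IBS")) + b[i]
      data.frame(participant_id = ids[i], group = grp[i],
                 period = c("fasted", "fed"),
                 response = mu + stats::rnorm(2, 0, sd_resid),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
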