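# Statistical primitives used across the pipeline. The classical tests are
# thin wrappers around the corresponding stats:: routines with uniform
# result objects and explicit degenerate-input handling; the quasibinomial
# fitter is implemented here as IRLS with a free dispersion.

test_result <- function(statistic, p_value, df = NA_real_, n = NA_integer_,
                        method = "", degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, df = df, n = n,
                 method = method, degenerate = degenerate),
            class = "bisreact_test")
}

#' Two-tailed Welch t-test
#'
#' @param x,y Numeric samples.
#' @return A test-result list with \code{statistic}, \code{p_value},
#'   \code{df}, \code{n}, \code{method} and a \code{degenerate} flag (set
#'   instead of raising when both samples are constant).
#' @export
t_test_two_tailed <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x) + length(y)
  if (length(x) < 2L || length(y) < 2L)
    return(test_result(NA_real_, NA_real_, n = n, method = "Welch t-test",
                       degenerate = TRUE))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(test_result(if (eq) 0 else Inf, if (eq) 1 else 0, n = n,
                       method = "Welch t-test", degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter), n,
              "Welch t-test")
}

#' Chi-square goodness-of-fit test
#'
#' @param observed Observed counts.
#' @param expected Expected counts (same length; rescaled to
#'   \code{sum(observed)}). Continuity correction is off.
#' @return A test-result list.
#' @export
chi_square <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length", call. = FALSE)
  if (any(expected <= 0))
    return(test_result(NA_real_, NA_real_, method = "chi-square GOF",
                       degenerate = TRUE))
  e <- expected / sum(expected) * sum(observed)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  test_result(stat, stats::pchisq(stat, df, lower.tail = FALSE), df,
              sum(observed), "chi-square GOF")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; the normal approximation (with continuity
#' correction) is used above n = 25 or in the presence of ties.
#'
#' @param diffs Numeric vector of paired differences.
#' @return A test-result list.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[is.finite(diffs) & diffs != 0]
  if (length(d) < 2L)
    return(test_result(NA_real_, NA_real_, n = length(d),
                       method = "Wilcoxon signed-rank", degenerate = TRUE))
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result(unname(ht$statistic), ht$p.value, n = length(d),
              method = "Wilcoxon signed-rank")
}

#' Simple linear regression with Pearson correlation
#'
#' @param x Predictor.
#' @param y Response.
#' @return list with \code{slope}, \code{intercept}, \code{r}, \code{p}
#'   (two-sided, from the correlation t-test), \code{n}, and a
#'   \code{degenerate} flag when either variable has zero variance.
#' @export
pearson_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::var(x) == 0 || stats::var(y) == 0)
    return(list(slope = 0, intercept = if (n) mean(y) else NA_real_, r = 0,
                p = 1, n = n, degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, x), y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Quasibinomial GLM by IRLS
#'
#' Fits successes out of trials on a predictor matrix with a logit link and
#' a free dispersion. Convergence is declared when the relative deviance
#' change falls below \code{tol} (default 1e-8, max 100 iterations).
#' The dispersion is the Pearson chi-square divided by the residual degrees
#' of freedom; standard errors are scaled by its square root and p-values
#' use the t distribution on the residual df (matching
#' \code{glm(family = quasibinomial)}).
#'
#' @param y Successes.
#' @param m Trials (same length).
#' @param X Predictor matrix (include an intercept column explicitly).
#' @param tol Relative deviance-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class \code{bisreact_glm}: \code{coefficients} table
#'   (estimate, se, t, p), \code{dispersion}, \code{deviance},
#'   \code{fitted}, \code{n}, \code{df_residual}, \code{iterations}.
#' @export
quasibinomial_irls <- function(y, m, X, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (length(m) != n || nrow(X) != n)
    stop("y, m and X must have matching lengths", call. = FALSE)
  if (any(y < 0 | y > m)) stop("need 0 <= y <= m elementwise", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient predictor matrix (aliased: ",
         paste(drop, collapse = ", "), ")", call. = FALSE)
  }
  p <- ncol(X)
  # empirical-logit start
  mu <- (y + 0.5) / (m + 1)
  eta <- stats::qlogis(mu)
  beta <- qr.coef(qrX, eta)
  dev_fun <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / (m * mu)), 0)
    t2 <- ifelse(y < m, (m - y) * log((m - y) / (m - m * mu)), 0)
    2 * sum(t1 + t2)
  }
  mu_of <- function(b) pmin(pmax(stats::plogis(drop(X %*% b)), 1e-12),
                            1 - 1e-12)
  dev <- dev_fun(mu_of(beta))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- mu_of(beta)
    w <- m * mu * (1 - mu)
    z <- eta + (y - m * mu) / w
    beta <- stats::lm.wfit(X, z, w)$coefficients
    dev_new <- dev_fun(mu_of(beta))
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations (possible ",
         "separation; largest |coefficient|: ",
         signif(max(abs(beta)), 3), " at ",
         colnames(X)[which.max(abs(beta))], ")", call. = FALSE)
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  w <- m * mu * (1 - mu)
  df_res <- n - p
  pearson <- sum((y - m * mu)^2 / w)
  dispersion <- if (df_res > 0) pearson / df_res else NA_real_
  XtWX <- crossprod(X * sqrt(w))
  cov_unscaled <- chol2inv(chol(XtWX))
  se <- sqrt(diag(cov_unscaled) * dispersion)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    dispersion = dispersion, deviance = dev, fitted = mu, n = n,
    df_residual = df_res, iterations = iter
  ), class = "bisreact_glm")
}

#' @export
print.bisreact_glm <- function(x, ...) {
  cat("Quasibinomial GLM (logit link), n =", x$n, "\n")
  cat("Dispersion:", signif(x$dispersion, 4), " Deviance:",
      signif(x$deviance, 6), "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
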