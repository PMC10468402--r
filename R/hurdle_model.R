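#' @importFrom stats glm.fit lm.fit binomial pchisq p.adjust optim plogis
NULL

# Minimum number of detected cells for the continuous part to be fit.
.hurdle_kmin <- 3L

# Numerically stable softplus, log(1 + exp(x)).
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmax(x, -30))))

# Logistic log-likelihood at linear predictor eta for 0/1 response.
.logis_ll <- function(eta, z) sum(z * eta - .softplus(eta))

# Penalized logistic fallback used when IRLS separates: tiny L2 ridge
# keeps the optimum finite and the fit deterministic. The reported
# log-likelihood is the unpenalized one at the penalized optimum.
.logistic_penalized <- function(X, z, lambda = 1e-6) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -.logis_ll(eta, z) + lambda * sum(b^2)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    -drop(crossprod(X, z - stats::plogis(eta))) + 2 * lambda * b
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  list(coef = fit$par, loglik = .logis_ll(drop(X %*% fit$par), z))
}

# Fit one part-pair hurdle model on a prebuilt design matrix.
# X: n x p full-rank-or-pivoted design with intercept; y: lognorm values.
.hurdle_fit_mat <- function(y, X, k_min = .hurdle_kmin) {
  n <- length(y)
  z <- as.numeric(y > 0)
  nd <- sum(z)
  disc <- list(coef = NULL, loglik = 0, df = 0L, degenerate = TRUE,
               separated = FALSE)
  cont <- list(coef = NULL, sigma2 = NA_real_, loglik = 0, df = 0L,
               degenerate = TRUE)

  if (nd > 0 && nd < n) {
    fit <- suppressWarnings(stats::glm.fit(X, z, family = stats::binomial()))
    cf <- fit$coefficients
    ok <- !is.na(cf)
    mu <- fit$fitted.values
    separated <- !fit$converged || any(abs(cf[ok]) > 15) ||
      all(mu[z == 1] > 1 - 1e-8) && all(mu[z == 0] < 1e-8)
    if (separated) {
      Xk <- X[, ok, drop = FALSE]
      pf <- .logistic_penalized(Xk, z)
      cf[ok] <- pf$coef
      ll <- pf$loglik
    } else {
      ll <- -fit$deviance / 2
    }
    disc <- list(coef = cf, loglik = ll, df = sum(ok), degenerate = FALSE,
                 separated = separated)
  }

  if (nd >= k_min) {
    idx <- which(z == 1)
    Xd <- X[idx, , drop = FALSE]
    fit <- stats::lm.fit(Xd, y[idx])
    rss <- sum(fit$residuals^2)
    if (rss > 1e-12 * max(1, sum(y[idx]^2))) {
      sigma2 <- rss / nd                       # ML variance
      ll <- -nd / 2 * (log(2 * pi * sigma2) + 1)
      cont <- list(coef = fit$coefficients, sigma2 = sigma2, loglik = ll,
                   df = sum(!is.na(fit$coefficients)) + 1L,  # + sigma
                   degenerate = FALSE)
    }
  }

  structure(list(discrete = disc, continuous = cont, n = n, n_detected = nd,
                 colnames = colnames(X)),
            class = "HurdleFit")
}

#' Fit a two-part hurdle model to one gene
#'
#' The hurdle model decomposes single-cell expression into a discrete
#' part — logistic regression of the detection indicator `1[y > 0]` on
#' the design — and a continuous part — Gaussian linear regression of
#' the log-normalized expression on the same design, restricted to
#' detected cells. The two parts are fit independently by maximum
#' likelihood; the model log-likelihood is their sum, which is what
#' [hurdle_lrt()] compares between nested designs.
#'
#' Degenerate situations are flagged rather than fatal: a gene detected
#' in all or no cells has no discrete information (0 df); fewer than
#' `k_min` detected cells, or zero residual variance, disables the
#' continuous part. Perfect separation in the logistic part triggers a
#' deterministic ridge-penalized refit (flagged `separated`).
#'
#' @param y numeric vector of log-normalized expression, one per cell.
#' @param data data.frame of per-cell covariates.
#' @param formula right-hand-side formula over `data` columns, e.g.
#'   `~ cdr + condition + target`.
#' @param k_min minimum detected cells for the continuous part
#'   (default 3).
#' @return `HurdleFit`: per-part coefficients, log-likelihood, df
#'   (number of estimated parameters; the continuous df includes the
#'   variance), and degeneracy/separation flags.
#' @export
fit_hurdle <- function(y, data, formula, k_min = .hurdle_kmin) {
  stopifnot(length(y) >= 2, length(y) == nrow(data))
  X <- stats::model.matrix(formula, data)
  .hurdle_fit_mat(y, X, k_min = k_min)
}

#' @export
print.HurdleFit <- function(x, ...) {
  cat(sprintf(
    "HurdleFit: n = %d (%d detected); logLik disc %.3f (df %d%s), cont %.3f (df %d)\n",
    x$n, x$n_detected, x$discrete$loglik, x$discrete$df,
    if (isTRUE(x$discrete$separated)) ", separated" else "",
    x$continuous$loglik, x$continuous$df))
  invisible(x)
}

#' Total hurdle log-likelihood
#'
#' @param fit `HurdleFit`.
#' @return discrete + continuous log-likelihood (degenerate parts
#'   contribute 0).
#' @export
hurdle_loglik <- function(fit) fit$discrete$loglik + fit$continuous$loglik

#' Likelihood-ratio test between nested hurdle fits
#'
#' The statistic is twice the summed log-likelihood gain over both
#' parts, clipped at zero; its degrees of freedom are the number of
#' parameters dropped, summed over the parts in which both fits are
#' non-degenerate. A part degenerate in either fit contributes neither
#' likelihood nor df. When no part is comparable the test is reported
#' `degenerate` with p = 1.
#'
#' @param full,reduced `HurdleFit` objects on the same cells; the
#'   reduced design must nest in the full design.
#' @return list: `chisq`, `df`, `p`, `status` (`"ok"` or
#'   `"degenerate"`).
#' @export
hurdle_lrt <- function(full, reduced) {
  stat <- 0
  df <- 0L
  if (!full$discrete$degenerate && !reduced$discrete$degenerate) {
    stat <- stat + 2 * (full$discrete$loglik - reduced$discrete$loglik)
    df <- df + (full$discrete$df - reduced$discrete$df)
  }
  if (!full$continuous$degenerate && !reduced$continuous$degenerate) {
    stat <- stat + 2 * (full$continuous$loglik - reduced$continuous$loglik)
    df <- df + (full$continuous$df - reduced$continuous$df)
  }
  stat <- max(stat, 0)
  if (df <= 0) return(list(chisq = stat, df = 0L, p = 1, status = "degenerate"))
  list(chisq = stat, df = as.integer(df),
       p = stats::pchisq(stat, df = df, lower.tail = FALSE), status = "ok")
}

#' Model-based log2 fold change for a binary contrast
#'
#' Combines the two hurdle parts into a single effect size: the
#' difference in predicted expression between the two levels of the
#' contrast column, evaluated with every other covariate at its mean,
#' converted to the log2 scale. Predicted expression is
#' `P(detect) x E[y | detected]`, so the discrete-part effect is
#' propagated through the detection probability at the mean detection
#' rate. With `mode = "continuous"` only the continuous-part
#' coefficient (rescaled to log2) is reported.
#'
#' @param fit full-model `HurdleFit`.
#' @param X design matrix the fit was produced on.
#' @param contrast_col name of the 0/1 contrast column in `X`.
#' @param mode `"combined"` (default) or `"continuous"`.
#' @return log2 fold change (finite; 0 for fully degenerate fits).
#' @export
hurdle_log2fc <- function(fit, X, contrast_col, mode = c("combined",
                                                         "continuous")) {
  mode <- match.arg(mode)
  if (!contrast_col %in% fit$colnames) return(0)
  j <- match(contrast_col, fit$colnames)
  cc <- fit$continuous$coef
  beta_c <- if (!fit$continuous$degenerate && !is.na(cc[j])) cc[j] else 0
  if (mode == "continuous") return(beta_c / log(2))
  xbar <- colMeans(X)
  x0 <- xbar; x0[j] <- 0
  x1 <- xbar; x1[j] <- 1
  pred <- function(x) {
    p <- 1
    if (!fit$discrete$degenerate) {
      cf <- fit$discrete$coef; cf[is.na(cf)] <- 0
      p <- stats::plogis(sum(cf * x))
    }
    mu <- 0
    if (!fit$continuous$degenerate) {
      cf <- cc; cf[is.na(cf)] <- 0
      mu <- sum(cf * x)
    }
    p * mu
  }
  (pred(x1) - pred(x0)) / log(2)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the two
#' procedures used here. Missing p-values are excluded from the family
#' size and returned missing.
#'
#' @param p numeric vector of p-values (NAs allowed).
#' @param method `"BH"` (Benjamini-Hochberg step-up, the per-test-family
#'   FDR) or `"bonferroni"` (used for response scores).
#' @return adjusted p-values, same length and NA pattern as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- p
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = method)  # family = tested genes
  out
}

# Run full/reduced hurdle LRTs for every gene (column) of a lognorm
# matrix against prebuilt design matrices. Returns the standard
# per-gene result table. contrast_col names the single column whose
# effect size is reported (NA -> log2fc 0).
.hurdle_test_genes <- function(lognorm, genes, X_full, X_red,
                               contrast_col = NA_character_,
                               log2fc_mode = "combined",
                               k_min = .hurdle_kmin) {
  res <- data.frame(gene = genes, chisq = NA_real_, df = NA_integer_,
                    p = NA_real_, log2fc = NA_real_, fdr = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    y <- lognorm[, genes[k]]
    if (methods::is(y, "sparseVector") || inherits(y, "Matrix"))
      y <- as.numeric(y)
    full <- .hurdle_fit_mat(y, X_full, k_min = k_min)
    red <- .hurdle_fit_mat(y, X_red, k_min = k_min)
    tst <- hurdle_lrt(full, red)
    l2fc <- if (is.na(contrast_col)) 0 else
      hurdle_log2fc(full, X_full, contrast_col, mode = log2fc_mode)
    res$chisq[k] <- tst$chisq
    res$df[k] <- tst$df
    res$p[k] <- if (tst$status == "ok") tst$p else NA_real_
    res$log2fc[k] <- l2fc
    res$status[k] <- tst$status
  }
  res$fdr <- adjust_pvalues(res$p, "BH")
  res
}
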