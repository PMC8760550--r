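# design matrix for the covariate model; errors on rank deficiency
covar_design <- function(samples, covars) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(samples[, covars, drop = FALSE]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient covariate design (constant or collinear covariate)")
  }
  X
}

# log-scale values regardless of container scale
log_values <- function(x) if (x$scale == "log") x$values else log(x$values)

#' Pre-clustering covariate scan
#'
#' Fits, per antibody, one joint ordinary-least-squares model of log MFI on
#' BMI, age and entry date, and reports two-sided per-coefficient p-values
#' plus the count of antibodies significant at p < 0.05 for each covariate.
#' Samples with any missing covariate are dropped first.
#'
#' @param x an [mfi_matrix()].
#' @param covars covariate column names in the sample table.
#' @param roles sample roles entering the scan.
#' @return a `covariate_scan` list: `pvalues` (antibodies x covariates),
#'   `coefficients`, `counts` of p < 0.05 per covariate, `n_used`.
#' @export
covariate_scan <- function(x, covars = c("bmi", "age", "entry_date"),
                           roles = c("study", "double")) {
  stopifnot(inherits(x, "mfi_matrix"))
  s <- x$samples
  use <- s$role %in% roles & complete.cases(s[, covars, drop = FALSE])
  if (sum(use) <= length(covars) + 1) stop("too few complete samples")
  X <- covar_design(s[use, , drop = FALSE], covars)
  Y <- log_values(x)[use, , drop = FALSE]

  qrX <- qr(X)
  B <- qr.coef(qrX, Y)                     # (1+q) x p
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tval <- B / se
  pval <- 2 * pt(-abs(tval), df)
  pv <- t(pval[covars, , drop = FALSE])
  structure(list(pvalues = pv,
                 coefficients = t(B[covars, , drop = FALSE]),
                 counts = colSums(pv < 0.05),
                 n_used = nrow(X), covars = covars),
            class = "covariate_scan")
}

#' @export
print.covariate_scan <- function(x, ...) {
  cat(sprintf("covariate scan on %d samples, %d antibodies\n",
              x$n_used, nrow(x$pvalues)))
  cat("antibodies with p < 0.05:\n")
  print(x$counts)
  invisible(x)
}

#' Residualize protein levels on covariates
#'
#' Per antibody, replaces log MFI by the OLS residual plus the fitted
#' intercept (location preserved), i.e. subtracts the estimated covariate
#' contributions. Coefficients are estimated on study samples only; held-out
#' samples (doubles, replicates) are adjusted with the study-sample
#' coefficients. Samples missing a covariate are dropped.
#'
#' @inheritParams covariate_scan
#' @param fit_roles roles used to estimate the coefficients.
#' @param adjust_roles roles retained (and adjusted) in the output.
#' @return a log-scale [mfi_matrix()] of adjusted values.
#' @export
residualize <- function(x, covars = c("bmi", "age", "entry_date"),
                        fit_roles = "study",
                        adjust_roles = c("study", "double", "replicate")) {
  stopifnot(inherits(x, "mfi_matrix"))
  s <- x$samples
  complete <- complete.cases(s[, covars, drop = FALSE])
  fit_use <- s$role %in% fit_roles & complete
  out_use <- s$role %in% adjust_roles & complete
  if (sum(fit_use) <= length(covars) + 1) stop("too few complete samples")
  X <- covar_design(s[fit_use, , drop = FALSE], covars)
  Y <- log_values(x)[fit_use, , drop = FALSE]
  B <- qr.coef(qr(X), Y)
  slopes <- B[covars, , drop = FALSE]

  Z <- as.matrix(s[out_use, covars, drop = FALSE])
  storage.mode(Z) <- "double"
  adj <- log_values(x)[out_use, , drop = FALSE] - Z %*% slopes
  mfi_matrix(adj, s[out_use, , drop = FALSE], scale = "log")
}
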