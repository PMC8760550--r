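#' Conditional logistic regression for 1:M matched sets
#'
#' Maximizes the conditional likelihood
#' `L(beta) = prod_s exp(eta_case) / sum_{l in s} exp(eta_l)` over matched
#' sets with exactly one case each, by Newton-Raphson with step-halving
#' (start at beta = 0, convergence when the log-likelihood changes by less
#' than `tol`). Sets with a missing exposure value are dropped whole; sets
#' without within-set exposure variation are uninformative and contribute a
#' constant `-log |s|`.
#'
#' @param X numeric matrix of exposures (samples x terms).
#' @param case logical (or 0/1) case indicator per sample.
#' @param set_id matched-set identifier per sample.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return a `clogit_fit` list: `beta`, `se`, `z`, `p` (two-sided Wald),
#'   `loglik`, `loglik_null`, `n_sets`, `n_informative`, `converged`,
#'   `separation`.
#' @export
fit_clogit <- function(X, case, set_id, tol = 1e-10, max_iter = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  case <- as.logical(case)
  stopifnot(length(case) == nrow(X), length(set_id) == nrow(X))

  keep <- stats::ave(seq_along(set_id), set_id,
                     FUN = function(ix) all(is.finite(X[ix, ])) &&
                       sum(case[ix]) == 1 && length(ix) >= 2) == 1
  X <- X[keep, , drop = FALSE]; case <- case[keep]; set_id <- set_id[keep]
  sets <- split(seq_along(set_id), set_id)
  if (length(sets) == 0) stop("no usable matched sets")
  informative <- vapply(sets, function(ix)
    any(apply(X[ix, , drop = FALSE], 2, function(col) max(col) > min(col))), TRUE)
  q <- ncol(X)
  if (sum(informative) == 0) {
    # flat likelihood: maximum at beta = 0 by convention
    return(structure(list(beta = setNames(rep(0, q), colnames(X)),
                          se = setNames(rep(NA_real_, q), colnames(X)),
                          z = rep(NA_real_, q), p = rep(NA_real_, q),
                          loglik = -sum(log(vapply(sets, length, 1L))),
                          loglik_null = -sum(log(vapply(sets, length, 1L))),
                          n_sets = length(sets), n_informative = 0L,
                          converged = TRUE, separation = FALSE),
                     class = "clogit_fit"))
  }
  if (sum(informative) < 2) stop("need at least 2 informative matched sets")
  beta <- rep(0, q)
  loglik <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(vapply(sets, function(ix) {
      e <- eta[ix]; m <- max(e)
      e[case[ix]] - m - log(sum(exp(e - m)))
    }, 1.0))
  }
  score_info <- function(b) {
    eta <- as.numeric(X %*% b)
    g <- numeric(q); H <- matrix(0, q, q)
    for (ix in sets) {
      e <- eta[ix]; w <- exp(e - max(e)); w <- w / sum(w)
      Xs <- X[ix, , drop = FALSE]
      xbar <- colSums(w * Xs)
      g <- g + Xs[case[ix], ] - xbar
      H <- H + crossprod(Xs * sqrt(w)) - tcrossprod(xbar)
    }
    list(g = g, H = H)
  }

  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    si <- score_info(beta)
    step <- tryCatch(solve(si$H, si$g), error = function(e) NULL)
    if (is.null(step)) step <- as.numeric(MASS_ginv(si$H) %*% si$g)
    # step-halving keeps the log-likelihood non-decreasing
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    if (abs(ll_new - ll) < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  if (!converged) stop("conditional likelihood did not converge in ",
                       max_iter, " iterations")
  separation <- any(abs(beta) > 15)
  H <- score_info(beta)$H
  cov <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  structure(list(beta = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)), z = z,
                 p = 2 * pnorm(-abs(z)),
                 loglik = ll,
                 loglik_null = -sum(log(vapply(sets, length, 1L))),
                 n_sets = length(sets), n_informative = sum(informative),
                 converged = converged, separation = separation),
            class = "clogit_fit")
}

# Moore-Penrose inverse via SVD (fallback for a singular information matrix)
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("conditional logistic fit: %d sets (%d informative), loglik %.4f\n",
              x$n_sets, x$n_informative, x$loglik))
  print(data.frame(beta = x$beta, se = x$se, p = x$p))
  if (x$separation) cat("warning: possible complete separation\n")
  invisible(x)
}

# exposure specifications of the three case-control models
clogit_model_covars <- function(model) {
  switch(as.character(model),
         "1" = c("bmi", "entry_date"),
         "2" = c("bmi", "entry_date", "dense_area", "postmenopausal", "mht_ever"),
         "3" = c("bmi", "entry_date", "dense_area", "postmenopausal", "mht_ever",
                 "smoking", "alcohol", "parity_ever"),
         stop("unknown model: ", model))
}

# numeric covariate frame for the matched-set models (NA preserved)
clogit_covariate_frame <- function(samples) {
  data.frame(
    bmi = samples$bmi,
    entry_date = samples$entry_date,
    dense_area = samples$dense_area,
    postmenopausal = ifelse(is.na(samples$menopausal), NA,
                            as.numeric(samples$menopausal == "post")),
    mht_ever = ifelse(is.na(samples$mht_status), NA,
                      as.numeric(samples$mht_status %in% c("before", "current"))),
    smoking = samples$smoking,
    alcohol = samples$alcohol,
    parity_ever = ifelse(is.na(samples$parity), NA,
                         as.numeric(samples$parity == "ever")),
    row.names = samples$sample_id)
}

#' Screen proteins for case-control association
#'
#' Fits, per protein and per model, a conditional logistic regression of
#' case status on the (z-scaled) log protein level plus the model's
#' covariates across matched sets, with Benjamini-Hochberg adjustment of the
#' protein-term p-values across proteins within each model.
#'
#' @param x log-scale matrix or [mfi_matrix()] of QC-filtered protein levels.
#' @param samples sample annotations (must include `case_status`,
#'   `match_set_id` and the model covariates).
#' @param models subset of `c(1, 2, 3)`: model 1 adjusts for BMI and entry
#'   date; model 2 adds dense area, postmenopausal status and MHT ever-use;
#'   model 3 adds smoking, alcohol and parity.
#' @param standardize z-scale each protein before fitting.
#' @return a `clogit_screen` list: `table` (per protein x model: beta, p,
#'   fdr, n_sets), `summary` (nominal and FDR-significant counts per model),
#'   and `failures`.
#' @export
screen_proteins_clogit <- function(x, samples, models = c(1, 2, 3),
                                   standardize = TRUE) {
  if (length(models) == 0) stop("empty model list")
  v <- if (inherits(x, "mfi_matrix")) log_values(x) else as.matrix(x)
  if (inherits(x, "mfi_matrix")) samples <- x$samples
  stopifnot(nrow(samples) == nrow(v))
  study <- samples$case_status %in% c("case", "control") &
    !is.na(samples$match_set_id)
  v <- v[study, , drop = FALSE]
  samples <- samples[study, , drop = FALSE]
  case <- samples$case_status == "case"
  covar <- clogit_covariate_frame(samples)

  out <- list(); failures <- character(0)
  for (m in models) {
    cv <- clogit_model_covars(m)
    Xc <- as.matrix(covar[, cv, drop = FALSE])
    rows <- lapply(colnames(v), function(ab) {
      prot <- v[, ab]
      if (standardize) prot <- as.numeric(scale(prot))
      fit <- tryCatch(
        fit_clogit(cbind(protein = prot, Xc), case, samples$match_set_id),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <<- c(failures, sprintf("model %s / %s: %s", m, ab,
                                         conditionMessage(fit)))
        return(data.frame(model = m, antibody_id = ab, beta = NA_real_,
                          se = NA_real_, p = NA_real_, n_sets = NA_integer_))
      }
      data.frame(model = m, antibody_id = ab,
                 beta = fit$beta[["protein"]], se = fit$se[["protein"]],
                 p = fit$p[["protein"]], n_sets = fit$n_sets)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- p.adjust(tab$p, method = "BH")
    out[[as.character(m)]] <- tab
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab, tab$model), function(d) {
    data.frame(model = d$model[1], n_proteins = nrow(d),
               nominal = sum(d$p < 0.05, na.rm = TRUE),
               fdr_significant = sum(d$fdr < 0.05, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, failures = failures),
            class = "clogit_screen")
}

#' @export
print.clogit_screen <- function(x, ...) {
  cat("case-control protein screen\n")
  print(x$summary)
  if (length(x$failures)) {
    cat(length(x$failures), "per-protein fit failures\n")
  }
  invisible(x)
}
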