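# furthest-sum initialization: greedily pick rows maximizing the summed
# distance to the already chosen set, starting from a random row
furthest_sum_init <- function(X, k) {
  n <- nrow(X)
  n2 <- rowSums(X^2)
  chosen <- sample.int(n, 1)
  sumd <- rep(0, n)
  while (length(chosen) < k) {
    last <- chosen[length(chosen)]
    d2 <- pmax(n2 + n2[last] - 2 * as.numeric(X %*% X[last, ]), 0)
    sumd <- sumd + sqrt(d2)
    cand <- setdiff(which(sumd == max(sumd[-chosen])), chosen)
    if (length(cand) == 0) cand <- setdiff(order(-sumd), chosen)
    chosen <- c(chosen, cand[1])
  }
  chosen
}

penalty_weight <- function(X) 200 * max(abs(X), 1e-8)

#' Fit an archetypal analysis model
#'
#' Decomposes `X` (samples x features) as `X ~ alpha Z` with `Z = beta X`,
#' where the rows of `alpha` (sample weights on archetypes) and `beta`
#' (archetype weights on samples) are constrained to the probability simplex,
#' so archetypes are extreme points of the data's convex hull. Fitted by
#' alternating simplex-constrained least squares: each constrained row solve
#' uses non-negative least squares on a system augmented with a heavily
#' weighted sum-to-one row (penalty weight `200 * max|X|`). The best of
#' `restarts` furthest-sum-seeded starts is returned.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of archetypes (`1 <= k < n`).
#' @param max_iter maximum alternating iterations.
#' @param tol relative RSS decrease declaring convergence.
#' @param restarts number of random initializations.
#' @param seed integer seed controlling initialization.
#' @return an `archetype_model`: list with `k`, `Z` (k x p archetypes),
#'   `alpha` (n x k), `beta` (k x n), `rss`, `rss_history`, `n_iter`,
#'   `converged`, `seed`, `restarts`.
#' @export
fit_archetypes <- function(X, k, max_iter = 200, tol = 1e-6, restarts = 5,
                           seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1) stop("k must be >= 1")

  if (k == 1) {
    # the mean lies in the convex hull: closed form
    z <- colMeans(X)
    model <- list(k = 1L, Z = matrix(z, 1, dimnames = list(NULL, colnames(X))),
                  alpha = matrix(1, n, 1, dimnames = list(rownames(X), NULL)),
                  beta = matrix(1 / n, 1, n, dimnames = list(NULL, rownames(X))),
                  rss = sum(sweep(X, 2, z)^2),
                  rss_history = sum(sweep(X, 2, z)^2), n_iter = 0L,
                  converged = TRUE, seed = seed, restarts = 0L)
    return(structure(model, class = "archetype_model"))
  }

  M <- penalty_weight(X)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- furthest_sum_init(X, k)
      fit <- aa_fit_cpp(X, as.integer(init) - 1L, max_iter, tol, M)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
  })
  dimnames(best$alpha) <- list(rownames(X), NULL)
  dimnames(best$beta) <- list(NULL, rownames(X))
  colnames(best$Z) <- colnames(X)
  structure(list(k = as.integer(k), Z = best$Z, alpha = best$alpha,
                 beta = best$beta, rss = best$rss,
                 rss_history = best$history, n_iter = best$n_iter,
                 converged = best$converged, seed = seed,
                 restarts = as.integer(restarts)),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("archetype_model: k = %d, n = %d, p = %d, rss = %.6g (%s, %d iter)\n",
              x$k, nrow(x$alpha), ncol(x$Z), x$rss,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Unit-invariant knee of an RSS curve
#'
#' Scales both axes of the (k, rss) curve to `[0, 1]` and returns the point
#' with maximum perpendicular distance to the chord joining the endpoints.
#' Ties (including a perfectly linear decline, where every distance is 0) are
#' broken toward the smallest k.
#'
#' @param k_range increasing integer vector.
#' @param rss RSS per k.
#' @return list with `k_opt` and the per-point chord `distances`.
#' @export
knee_point <- function(k_range, rss) {
  stopifnot(length(k_range) == length(rss), length(k_range) >= 3,
            all(diff(k_range) > 0))
  u <- (k_range - k_range[1]) / (k_range[length(k_range)] - k_range[1])
  rng <- max(rss) - min(rss)
  w <- if (rng > 0) (rss - min(rss)) / rng else rep(0, length(rss))
  # distance from (u, w) to the chord from (u1, w1) to (un, wn)
  a <- w[length(w)] - w[1]; b <- -(u[length(u)] - u[1])
  cc <- -(a * u[1] + b * w[1])
  d <- abs(a * u + b * w + cc) / sqrt(a^2 + b^2)
  d[c(1, length(d))] <- 0
  k_opt <- k_range[which.max(d)]  # which.max takes the first (smallest k) tie
  if (max(d) < 1e-12) k_opt <- k_range[2]  # linear decline: first interior point
  list(k_opt = k_opt, distances = d)
}

#' Select the number of archetypes
#'
#' Fits the model for each k in `k_range`, records the best-of-restarts RSS,
#' and returns the unit-invariant knee of the (k, rss) curve. A k whose RSS
#' exceeds the previous k's is refitted once with doubled restarts; if the
#' curve remains non-monotone beyond tolerance an error asks for more
#' restarts.
#'
#' @inheritParams fit_archetypes
#' @param k_range increasing vector of candidate k.
#' @return list with `k_opt`, `k_range`, `rss` curve, chord `distances`, and
#'   the fitted `models`.
#' @export
select_k <- function(X, k_range = 2:10, max_iter = 200, tol = 1e-6,
                     restarts = 5, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(all(diff(k_range) > 0), max(k_range) < nrow(X))
  seeds <- if (is.null(seed)) rep(list(NULL), length(k_range)) else
    as.list(seed + seq_along(k_range))
  models <- vector("list", length(k_range))
  rss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    m <- fit_archetypes(X, k_range[i], max_iter, tol, restarts, seeds[[i]])
    if (i > 1 && m$rss > rss[i - 1]) {
      m2 <- fit_archetypes(X, k_range[i], max_iter, tol, 2 * restarts,
                           if (is.null(seeds[[i]])) NULL else seeds[[i]] + 7919L)
      if (m2$rss < m$rss) m <- m2
    }
    if (i > 1 && m$rss > rss[i - 1] * (1 + 1e-6)) {
      stop("RSS curve is non-monotone at k = ", k_range[i],
           "; refit with more restarts")
    }
    models[[i]] <- m
    rss[i] <- m$rss
  }
  kn <- knee_point(k_range, rss)
  list(k_opt = kn$k_opt, k_range = k_range, rss = rss,
       distances = kn$distances, models = models)
}

#' Hard cluster assignment from archetype coefficients
#'
#' Assigns each sample to the archetype with the largest coefficient; ties
#' are broken toward the lowest archetype index.
#'
#' @param model an `archetype_model`, or a bare `alpha` matrix.
#' @return data.frame with `sample_id`, `cluster` (in `1..k`) and
#'   `max_coefficient`.
#' @export
assign_clusters <- function(model) {
  alpha <- if (inherits(model, "archetype_model")) model$alpha else as.matrix(model)
  cl <- max.col(alpha, ties.method = "first")
  data.frame(sample_id = rownames(alpha) %||% as.character(seq_len(nrow(alpha))),
             cluster = cl,
             max_coefficient = alpha[cbind(seq_len(nrow(alpha)), cl)],
             stringsAsFactors = FALSE)
}

#' Predict archetype coefficients for held-out samples
#'
#' Solves the simplex-constrained least-squares projection of each new sample
#' onto the fixed, fitted archetypes (the archetypes are not refitted).
#'
#' @param model a fitted `archetype_model`.
#' @param X_new matrix with the same features as the training data.
#' @return matrix of coefficients (rows on the simplex).
#' @export
predict_coefficients <- function(model, X_new) {
  stopifnot(inherits(model, "archetype_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$Z)) {
    stop("X_new must have ", ncol(model$Z), " columns")
  }
  a <- aa_alpha_cpp(X_new, model$Z, penalty_weight(rbind(X_new, model$Z)))
  rownames(a) <- rownames(X_new)
  a
}
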