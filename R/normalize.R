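#' Antibody-specific probabilistic quotient normalization (Abs-PQN)
#'
#' Removes per-sample dilution effects within each 96-well plate. Working on
#' log intensities, the reference profile of a plate is the per-antibody
#' median over its (non-pool) samples. For each antibody, a similarity set of
#' the `n_similar` antibodies most rank-correlated with it (itself included)
#' defines a local dilution estimate: the per-sample factor is the median
#' quotient of the sample's values against the reference over that set, and
#' the antibody's values are divided by it. With `n_similar` equal to the
#' number of antibodies the method reduces to classical (global) PQN.
#'
#' Pool samples are excluded from the reference profile and the similarity
#' ranking but are transformed with their own quotients against the plate
#' reference.
#'
#' @param x an [mfi_matrix()] on the linear scale.
#' @param n_similar similarity-set size (clipped to the number of antibodies).
#' @return the normalized [mfi_matrix()]; shape and ordering preserved.
#' @export
abs_pqn <- function(x, n_similar = 50) {
  stopifnot(inherits(x, "mfi_matrix"))
  if (x$scale != "linear" || any(x$values <= 0)) {
    stop("abs_pqn requires strictly positive linear-scale MFI values")
  }
  v <- log(x$values)
  p <- ncol(v)
  n_similar <- max(1L, min(as.integer(n_similar), p))
  ab_ids <- colnames(v)
  plates <- split(seq_len(nrow(v)), x$samples$plate_id)
  out <- v
  for (ix in plates) {
    ref_ix <- ix[x$samples$role[ix] != "pool"]
    if (length(ref_ix) < 3) {
      stop("each plate needs at least 3 non-pool samples for Abs-PQN")
    }
    r <- apply(v[ref_ix, , drop = FALSE], 2, median)
    q <- sweep(v[ix, , drop = FALSE], 2, r)  # log quotients vs reference
    if (n_similar >= p) {
      sim_sets <- replicate(p, seq_len(p), simplify = FALSE)
    } else {
      rho <- suppressWarnings(
        cor(v[ref_ix, , drop = FALSE], method = "spearman"))
      rho[!is.finite(rho)] <- -Inf
      sim_sets <- lapply(seq_len(p), function(j) {
        # ties in correlation broken by antibody id order; j always included
        ord <- order(-rho[, j], ab_ids)
        head(unique(c(j, ord)), n_similar)
      })
    }
    for (j in seq_len(p)) {
      f <- apply(q[, sim_sets[[j]], drop = FALSE], 1, median)
      out[ix, j] <- v[ix, j] - f
    }
  }
  mfi_matrix(exp(out), x$samples, scale = "linear")
}

#' Between-plate MA normalization
#'
#' Removes intensity-dependent plate effects. For each plate, per-antibody
#' plate medians of log intensity are contrasted with the global per-antibody
#' median (over all non-pool samples): `M` is their difference and `A` their
#' mean. A locally weighted regression of M on A across antibodies (span =
#' `span`) is fitted per plate and the fitted offset is subtracted from every
#' log intensity of the plate at that antibody.
#'
#' @param x an [mfi_matrix()] on the linear scale with at least 2 plates.
#' @param span lowess smoothing span.
#' @return the normalized [mfi_matrix()].
#' @export
ma_normalize <- function(x, span = 0.3) {
  stopifnot(inherits(x, "mfi_matrix"))
  if (x$scale != "linear" || any(x$values <= 0)) {
    stop("ma_normalize requires strictly positive linear-scale MFI values")
  }
  if (ncol(x$values) < 10) stop("MA smoothing needs at least 10 antibodies")
  plates <- split(seq_len(nrow(x$values)), x$samples$plate_id)
  if (length(plates) < 2) stop("MA normalization needs at least 2 plates")
  v <- log(x$values)
  not_pool <- x$samples$role != "pool"
  g <- apply(v[not_pool, , drop = FALSE], 2, median)
  out <- v
  for (ix in plates) {
    ref_ix <- ix[x$samples$role[ix] != "pool"]
    m_plate <- apply(v[ref_ix, , drop = FALSE], 2, median)
    M <- m_plate - g
    A <- (m_plate + g) / 2
    lo <- lowess(A, M, f = span)
    fit <- approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
    out[ix, ] <- sweep(v[ix, , drop = FALSE], 2, fit)
  }
  mfi_matrix(exp(out), x$samples, scale = "linear")
}
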