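#' Jaccard index of two sets
#'
#' `|A n B| / |A u B|`; defined as 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap cluster stability (mean Jaccard index)
#'
#' Repeats the archetypal clustering `B` times on bootstrap resamples of the
#' rows of `X` (same k as the reference clustering). For each repetition and
#' each reference cluster, the Jaccard index against the most similar
#' bootstrap cluster is computed on the set of distinct drawn samples; the
#' per-cluster mean over repetitions is the MJI.
#'
#' @param X the matrix that was clustered (samples x features).
#' @param k number of archetypes; taken from `ref_model` when supplied.
#' @param B bootstrap repetitions.
#' @param seed integer seed for the resampling and refit stream.
#' @param ref_model optional fitted reference `archetype_model` on `X`.
#' @param restarts restarts per bootstrap refit.
#' @param max_iter,tol passed to [fit_archetypes()].
#' @return a `stability_result`: `mji_mean` and `mji_sd` per reference
#'   cluster, the B x k matrix of matched Jaccard values, `B`, `k`.
#' @export
bootstrap_mji <- function(X, k = NULL, B = 150, seed = NULL, ref_model = NULL,
                          restarts = 2, max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X)
  if (B < 1) stop("B must be >= 1")
  if (is.null(ref_model)) {
    if (is.null(k)) stop("supply k or a reference model")
    ref_model <- fit_archetypes(X, k, max_iter, tol, restarts = 5, seed = seed)
  }
  k <- ref_model$k
  n <- nrow(X)
  ref_cl <- assign_clusters(ref_model)$cluster
  ref_sets <- split(seq_len(n), factor(ref_cl, levels = seq_len(k)))

  jac <- matrix(NA_real_, B, k)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(
        fit_archetypes(X[idx, , drop = FALSE], k, max_iter, tol, restarts),
        error = function(e) NULL)
      if (is.null(fit)) {
        fit <- fit_archetypes(X[idx, , drop = FALSE], k, max_iter, tol,
                              restarts + 2)
      }
      dist_pos <- !duplicated(idx)        # distinct drawn samples
      d_samples <- idx[dist_pos]
      boot_cl <- assign_clusters(fit)$cluster[dist_pos]
      boot_sets <- split(d_samples, factor(boot_cl, levels = seq_len(k)))
      for (cl in seq_len(k)) {
        ref_d <- intersect(ref_sets[[cl]], d_samples)
        jac[b, cl] <- max(vapply(boot_sets, jaccard, 1.0, b = ref_d))
      }
    }
  })
  structure(list(mji_mean = colMeans(jac), mji_sd = apply(jac, 2, sd),
                 jaccard = jac, B = B, k = k, ref_model = ref_model),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("bootstrap stability, B = %d, k = %d\n", x$B, x$k))
  for (cl in seq_len(x$k)) {
    cat(sprintf("  cluster %d: MJI = %.2f +/- %.2f\n",
                cl, x$mji_mean[cl], x$mji_sd[cl]))
  }
  invisible(x)
}

#' Same-cluster concordance of replicate, double, and random pairs
#'
#' Computes, for each pair type, the fraction of pairs whose two members are
#' assigned to the same cluster, and compares the pair types with two-sided
#' Fisher exact tests on the 2 x 2 tables (same/different x type A/type B).
#' Random pairs are drawn without replacement among study samples.
#'
#' @param labels named vector of cluster labels covering all pair members and
#'   the study samples.
#' @param replicate_pairs,double_pairs data.frames with `first`/`second`
#'   sample-id columns.
#' @param study_ids sample ids from which random pairs are drawn.
#' @param n_random_pairs number of random pairs.
#' @param seed integer seed for the random pairs.
#' @return a `concordance_result`: per-type counts and rates, and the Fisher
#'   p-value per type comparison.
#' @export
pair_concordance <- function(labels, replicate_pairs, double_pairs, study_ids,
                             n_random_pairs = 100, seed = NULL) {
  if (nrow(replicate_pairs) == 0 || nrow(double_pairs) == 0) {
    stop("replicate and double pair lists must be non-empty")
  }
  if (2 * n_random_pairs > length(study_ids)) {
    stop("not enough study samples for ", n_random_pairs,
         " disjoint random pairs")
  }
  same <- function(pairs) {
    if (!all(c(pairs$first, pairs$second) %in% names(labels))) {
      stop("labels must cover all pair members")
    }
    labels[pairs$first] == labels[pairs$second]
  }
  rnd_ids <- with_seed(seed, sample(study_ids, 2 * n_random_pairs))
  random_pairs <- data.frame(first = rnd_ids[seq_len(n_random_pairs)],
                             second = rnd_ids[n_random_pairs + seq_len(n_random_pairs)])
  ind <- list(replicate = same(replicate_pairs), double = same(double_pairs),
              random = same(random_pairs))
  counts <- vapply(ind, sum, 1L)
  totals <- vapply(ind, length, 1L)
  cmp <- utils::combn(names(ind), 2, simplify = FALSE)
  pvals <- vapply(cmp, function(ab) {
    tab <- rbind(c(counts[ab[1]], totals[ab[1]] - counts[ab[1]]),
                 c(counts[ab[2]], totals[ab[2]] - counts[ab[2]]))
    fisher.test(tab)$p.value
  }, 1.0)
  names(pvals) <- vapply(cmp, paste, "", collapse = "_vs_")
  structure(list(same_cluster = counts, n_pairs = totals,
                 rate = counts / totals, fisher_p = pvals,
                 random_pairs = random_pairs),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("same-cluster rates:\n")
  for (t in names(x$rate)) {
    cat(sprintf("  %-9s %d/%d = %.2f\n", t, x$same_cluster[t], x$n_pairs[t],
                x$rate[t]))
  }
  cat("pairwise Fisher p:\n")
  for (t in names(x$fisher_p)) cat(sprintf("  %s: %.3g\n", t, x$fisher_p[t]))
  invisible(x)
}
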