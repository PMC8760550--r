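# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately brute-force / closed-form and shares no code
# with the package implementation it checks.

# all permutations of a vector (k is always small in these tests)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (q in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], q)
  }
  out
}

cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# mean cosine similarity between two k x p matrices after the best row matching
match_cosine <- function(A, B) {
  k <- nrow(A)
  cmat <- outer(seq_len(k), seq_len(k),
                Vectorize(function(i, j) cos_sim(A[i, ], B[j, ])))
  max(vapply(perms(seq_len(k)),
             function(p) mean(cmat[cbind(seq_len(k), p)]), 1.0))
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# classical (global) probabilistic quotient normalization, per plate
pqn_classic <- function(x) {
  v <- log(mfi_values(x))
  s <- mfi_samples(x)
  for (pl in unique(s$plate_id)) {
    ix <- which(s$plate_id == pl)
    ref_ix <- ix[s$role[ix] != "pool"]
    r <- apply(v[ref_ix, , drop = FALSE], 2, median)
    f <- apply(sweep(v[ix, , drop = FALSE], 2, r), 1, median)
    v[ix, ] <- v[ix, , drop = FALSE] - f
  }
  exp(v)
}

# brute-force Benjamini-Hochberg step-up adjusted p-values
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    vals <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, 1.0)
    adj[i] <- min(1, min(vals))
  }
  adj
}

# two-sided Fisher exact p for a 2x2 table by direct hypergeometric summation
fisher2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# projected-gradient archetypal analysis (independent of the package solver):
# alternating gradient steps on alpha and beta with Euclidean simplex
# projection (Duchi et al. 2008), fixed step sizes from Lipschitz bounds
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - 1) / seq_along(u)))
  pmax(v - (css[rho] - 1) / rho, 0)
}

pg_archetypes <- function(X, k, init_rows, n_iter = 2000) {
  n <- nrow(X)
  beta <- matrix(0, k, n)
  beta[cbind(seq_len(k), init_rows)] <- 1
  alpha <- matrix(1 / k, n, k)
  rss_of <- function(al, be) sum((X - al %*% be %*% X)^2)
  f <- rss_of(alpha, beta)
  t_a <- 1e-3; t_b <- 1e-6   # adaptive step sizes with backtracking
  for (it in seq_len(n_iter)) {
    Z <- beta %*% X
    grad_a <- 2 * (alpha %*% Z - X) %*% t(Z)
    repeat {
      cand <- t(apply(alpha - t_a * grad_a, 1, proj_simplex))
      f_new <- rss_of(cand, beta)
      if (f_new <= f || t_a < 1e-14) break
      t_a <- t_a / 2
    }
    if (f_new <= f) { alpha <- cand; f <- f_new; t_a <- t_a * 1.3 }

    R <- alpha %*% beta %*% X - X
    grad_b <- 2 * t(alpha) %*% R %*% t(X)
    repeat {
      cand <- t(apply(beta - t_b * grad_b, 1, proj_simplex))
      f_new <- rss_of(alpha, cand)
      if (f_new <= f || t_b < 1e-16) break
      t_b <- t_b / 2
    }
    if (f_new <= f) { beta <- cand; f <- f_new; t_b <- t_b * 1.3 }
  }
  Z <- beta %*% X
  list(alpha = alpha, beta = beta, Z = Z, rss = rss_of(alpha, beta))
}

# Gaussian point clouds around well-separated centers (rows = samples);
# returns the matrix and the true cloud labels
make_clouds <- function(n_per, centers, noise_sd, seed) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    X <- do.call(rbind, lapply(seq_len(k), function(c)
      matrix(rnorm(n_per * ncol(centers), 0, noise_sd), n_per) +
        matrix(centers[c, ], n_per, ncol(centers), byrow = TRUE)))
    list(X = X, labels = rep(seq_len(k), each = n_per))
  })
}

# small generator configuration with all defect/duplicate machinery off
quiet_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cases = 30, n_doubles = 6, n_replicate_pairs = 6,
                   n_antibodies = 80, n_planted_archetypes = 3,
                   n_duplicate_targets = 0, seed = 1)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
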