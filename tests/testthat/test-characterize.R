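test_that("fisher_exact_rxc matches the hypergeometric oracle and handles r x c", {
  # 2 x 2 agreement with the closed-form oracle to 1e-12
  tabs <- withr::with_seed(1, replicate(20, matrix(rpois(4, 8) + 1, 2),
                                        simplify = FALSE))
  for (tab in tabs) {
    expect_equal(fisher_exact_rxc(tab)$p, fisher2x2_oracle(tab),
                 tolerance = 1e-12)
  }
  # diagonal table: p = 2 / choose(20, 10)
  expect_equal(fisher_exact_rxc(matrix(c(10, 0, 0, 10), 2))$p,
               2 / choose(20, 10), tolerance = 1e-12)

  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero-margin")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  # Monte Carlo converges: doubling draws moves p by < 3 MC standard errors
  tab3 <- matrix(c(86, 15, 19, 186, 32, 33), nrow = 3)
  p1 <- fisher_exact_rxc(tab3, method = "montecarlo", mc_draws = 2e4, seed = 1)
  p2 <- fisher_exact_rxc(tab3, method = "montecarlo", mc_draws = 4e4, seed = 2)
  se <- sqrt(p1$p * (1 - p1$p) / 2e4)
  expect_lt(abs(p1$p - p2$p), 3 * (se + sqrt(p2$p * (1 - p2$p) / 4e4)))
  # and sits near the exact network value
  expect_lt(abs(p1$p - fisher_exact_rxc(tab3)$p), 4 * se)
})

test_that("clinical tests route variables to the right test and stay calibrated", {
  labels <- rep(1:3, c(40, 80, 80))
  n <- length(labels)
  # 100 null continuous variables: cluster-1-vs-rest p-values uniform
  ann <- withr::with_seed(2, as.data.frame(matrix(rnorm(n * 100), n)))
  names(ann) <- sprintf("v%03d", 1:100)
  vars <- setNames(rep("continuous", 100), names(ann))
  res <- cluster_clinical_tests(ann, labels, vars)
  p1 <- res$p[res$scope == "cluster 1 vs rest"]
  expect_length(p1, 100)
  expect_gt(suppressWarnings(ks.test(p1, "punif")$p.value), 0.01)

  # constant categorical variable: zero-margin error
  ann$flat <- "x"
  expect_error(cluster_clinical_tests(ann, labels, c(flat = "categorical")),
               "constant")

  # planted MHT-ever enrichment in a small cluster (odds ratio ~ 8)
  lab5 <- rep(1:5, c(19, 113, 115, 144, 182))
  pm <- ifelse(lab5 == 1, 0.79, 0.37)
  ann5 <- withr::with_seed(7, data.frame(
    mht_status = ifelse(runif(length(lab5)) < pm, "before", "never")))
  res5 <- cluster_clinical_tests(ann5, lab5, c(mht_status = "categorical"))
  pair_p <- res5$p[grepl("^cluster 1 vs [2-5]$", res5$scope)]
  expect_length(pair_p, 4)
  expect_true(all(pair_p < 0.05))
})

test_that("differential abundance: Welch t, BH agreement, planted power", {
  # identical groups: cluster duplicated into the rest -> all p near 1
  X0 <- withr::with_seed(3, matrix(rnorm(20 * 15), 20, 15,
                                   dimnames = list(NULL, sprintf("A%02d", 1:15))))
  Xdup <- rbind(X0, X0, X0)
  lab <- rep(c(1, 2, 2), each = 20)
  d0 <- differential_abundance(Xdup, lab, 1)
  expect_true(all(d0$p > 1 - 1e-8))
  expect_false(any(d0$fdr < 0.05))

  # per-antibody agreement with stats::t.test (Welch)
  Xr <- withr::with_seed(4, matrix(rnorm(60 * 5), 60, 5,
                                   dimnames = list(NULL, sprintf("A%02d", 1:5))))
  labr <- rep(c(1, 2), c(20, 40))
  dr <- differential_abundance(Xr, labr, 1)
  for (j in 1:5) {
    tt <- t.test(Xr[labr == 1, j], Xr[labr == 2, j])
    expect_equal(dr$p[j], tt$p.value, tolerance = 1e-12)
    expect_equal(dr$t_stat[j], unname(tt$statistic), tolerance = 1e-12)
  }
  # BH via brute-force step-up oracle (exact)
  expect_equal(dr$fdr, bh_bruteforce(dr$p), tolerance = 1e-14)

  # planted 1.5-sd shift on 40 of 200 antibodies
  res <- t(sapply(1:20, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(200 * 200), 200, 200,
                                    dimnames = list(NULL, sprintf("B%03d", 1:200))))
    lab <- rep(c(1, 2), c(30, 170))
    X[lab == 1, 1:40] <- X[lab == 1, 1:40] + 1.5
    d <- differential_abundance(X, lab, 1)
    c(tp = sum(d$fdr[1:40] < 0.05), fp = sum(d$fdr[-(1:40)] < 0.05))
  }))
  expect_gte(median(res[, "tp"]), 35)
  expect_lte(median(res[, "fp"]), 2)

  expect_error(differential_abundance(Xr, rep(c(1, 2), c(2, 58)), 1), ">= 3")
})

test_that("BH adjustment equals the brute-force step-up on short p-vectors", {
  for (s in 1:20) {
    p <- withr::with_seed(100 + s, runif(sample(3:20, 1))^2)
    expect_equal(p.adjust(p, method = "BH"), bh_bruteforce(p),
                 tolerance = 1e-14)
  }
})

test_that("shortlist takes the per-direction union of p and effect rankings", {
  mk <- function(p, diff) {
    structure(data.frame(antibody_id = sprintf("A%02d", seq_along(p)),
                         mean_diff = diff, t_stat = diff, p = p,
                         fdr = p, direction = ifelse(diff >= 0,
                                                     "higher_in_cluster",
                                                     "lower_in_cluster")),
              class = c("differential_result", "data.frame"))
  }
  # rankings agree: union collapses to m
  r1 <- mk(p = seq(0.01, 0.2, length.out = 20),
           diff = seq(2, 0.1, length.out = 20))
  s1 <- shortlist(r1, m = 5)
  expect_length(s1$higher, 5)
  # rankings disjoint: union has 2m members
  r2 <- mk(p = c(seq(0.001, 0.005, length.out = 5), rep(0.5, 5),
                 seq(0.01, 0.05, length.out = 10)),
           diff = c(rep(0.1, 5), seq(3, 2, length.out = 5), rep(0.2, 10)))
  s2 <- shortlist(r2, m = 5)
  expect_length(s2$higher, 10)
  # direction with fewer than m antibodies falls back with a warning
  r3 <- mk(p = c(0.1, 0.2, 0.3), diff = c(1, 1, -1))
  expect_warning(s3 <- shortlist(r3, m = 5), "fewer")
  expect_length(s3$higher, 2)
})

test_that("signed median fold change follows the sign-coded convention", {
  v <- matrix(rep(c(100, 200, 400), each = 4), 4)
  colnames(v) <- c("eq", "up", "dn")
  rownames(v) <- sprintf("S%d", 1:4)
  lab <- c(1, 1, 2, 2)
  v[lab == 1, "up"] <- v[lab == 1, "up"] * 2
  v[lab == 1, "dn"] <- v[lab == 1, "dn"] / 2
  fc <- median_fold_change(v, lab, 1)
  expect_equal(unname(fc), c(1, 2, -2))

  # planted 1.5x linear shift with low noise
  fcs <- vapply(1:20, function(s) {
    X <- withr::with_seed(s, matrix(exp(rnorm(100 * 1, 5, 0.1)), 100, 1,
                                    dimnames = list(NULL, "A")))
    lab <- rep(c(1, 2), c(30, 70))
    X[lab == 1, ] <- X[lab == 1, ] * 1.5
    median_fold_change(X, lab, 1)
  }, 1.0)
  expect_lt(abs(median(fcs) - 1.5), 0.1)

  expect_error(median_fold_change(v - 200, lab, 1), "positive")
})

test_that("trait associations are calibrated under the null and detect planted effects", {
  n <- 550
  ann <- withr::with_seed(5, data.frame(
    dense_area = rgamma(n, 1.35, scale = 20), bmi = rnorm(n, 25, 4),
    age = rnorm(n, 60, 9),
    mht_status = sample(c("never", "before", "current"), n, TRUE,
                        prob = c(0.47, 0.39, 0.14))))
  X <- withr::with_seed(6, matrix(rnorm(n * 100), n, 100,
                                  dimnames = list(NULL, sprintf("P%03d", 1:100))))
  ta <- trait_association(X, colnames(X), ann)
  ci <- qbinom(c(0.005, 0.995), 100, 0.05)
  expect_true(sum(ta$dense_area_sig) >= ci[1] && sum(ta$dense_area_sig) <= ci[2])
  expect_true(sum(ta$mht_sig) >= ci[1] && sum(ta$mht_sig) <= ci[2])

  # planted protein-MHT effect (log-odds -1 per sd): power > 0.9
  det <- vapply(1:30, function(j) {
    withr::with_seed(200 + j, {
      prot <- rnorm(n)
      a2 <- ann
      a2$mht_status <- ifelse(rbinom(n, 1, plogis(-0.2 - prot)) == 1,
                              "before", "never")
      trait_association(matrix(prot, dimnames = list(NULL, "P1")), "P1",
                        a2)$mht_sig
    })
  }, TRUE)
  expect_gt(mean(det), 0.9)

  ann_bad <- ann
  ann_bad$mht_status <- NA
  expect_error(trait_association(X, "P001", ann_bad), "missing")
})
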