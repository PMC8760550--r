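# hand-built container with study samples and replicate pairs
qc_toy <- function(n_study = 10, n_pairs = 4, p = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_study + 2 * n_pairs
    ids <- sprintf("S%02d", seq_len(n))
    roles <- c(rep("study", n_study), rep("replicate", 2 * n_pairs))
    subj <- c(sprintf("u%02d", seq_len(n_study)),
              rep(sprintf("r%02d", seq_len(n_pairs)), 2))
    v <- matrix(exp(rnorm(n * p, 7, 0.5)), n, p,
                dimnames = list(ids, sprintf("AB%02d", seq_len(p))))
    list(x = mfi_matrix(v, data.frame(sample_id = ids, plate_id = "p1",
                                      role = roles, subject_id = subj)),
         igg = setNames(exp(rnorm(n, 5, 0.5)), ids))
  })
}

test_that("compute_qc evaluates the three exclusion criteria as printed", {
  toy <- qc_toy()
  x <- toy$x
  pairs <- replicate_pairs_from_samples(x$samples)
  # AB01: identical replicate members -> rho 1; AB02: anti-correlated
  x$values[pairs$second, "AB01"] <- x$values[pairs$first, "AB01"]
  x$values[pairs$second, "AB02"] <- max(x$values) + 1 -
    x$values[pairs$first, "AB02"]
  study <- x$samples$sample_id[x$samples$role == "study"]
  # AB03: background just past mean + 3 sd; others far below
  x$values[study, "AB03"] <- 1000 * exp(rnorm(length(study), 0, 1e-3))
  sm <- colMeans(x$values[study, ])
  ss <- apply(x$values[study, ], 2, sd)
  empty <- setNames(c(1, 1, sm["AB03"] + 3.5 * ss["AB03"]), colnames(x$values))

  rep <- compute_qc(x, pairs, igg_profile = toy$igg, empty_profile = empty)
  expect_equal(rep$replicate_rho[rep$antibody_id == "AB01"], 1)
  expect_false(rep$flagged[rep$antibody_id == "AB01"])
  expect_true(rep$low_reproducibility[rep$antibody_id == "AB02"])
  expect_true(rep$high_background[rep$antibody_id == "AB03"])

  # perfectly IgG-tracking antibody is flagged
  x2 <- toy$x
  x2$values[, "AB01"] <- toy$igg[rownames(x2$values)] * 3
  rep2 <- compute_qc(x2, pairs, igg_profile = toy$igg, empty_profile = empty)
  expect_true(rep2$igg_correlated[rep2$antibody_id == "AB01"])

  expect_error(compute_qc(x, pairs[1:2, ], toy$igg, empty), "3 replicate")
  expect_error(compute_qc(x, pairs, toy$igg, empty[1:2]), "antibody ids")
})

test_that("planted defects are all flagged with no false flags", {
  cfg <- simulation_config(n_cases = 60, n_doubles = 10, n_replicate_pairs = 48,
                           n_antibodies = 200, n_planted_archetypes = 3,
                           noise_sd = 0.1, n_bad_reproducibility = 5,
                           n_igg_correlated = 5, n_high_background = 5,
                           n_duplicate_targets = 10, seed = 11)
  sim <- generate_mfi(generate_cohort(cfg), cfg)
  xn <- ma_normalize(abs_pqn(sim$mfi), span = 0.3)
  rep <- compute_qc(xn, igg_profile = sim$igg_profile,
                    empty_profile = sim$empty_profile)
  planted <- sim$antibodies$planted_defect
  expect_equal(sum(rep$flagged & planted != "none"), 15)
  expect_equal(sum(rep$flagged & planted == "none"), 0)
  # flag classes match the planted classes
  expect_true(all(rep$low_reproducibility[planted == "bad_reproducibility"]))
  expect_true(all(rep$igg_correlated[planted == "igg_correlated"]))
  expect_true(all(rep$high_background[planted == "high_background"]))

  # apply_qc: survivors = unflagged minus extra duplicate-target antibodies
  xq <- apply_qc(xn, rep, sim$antibodies)
  surv <- sim$antibodies[!rep$flagged, ]
  expected <- length(unique(surv$target_gene))
  expect_equal(ncol(xq$values), expected)
  expect_false(anyDuplicated(sim$antibodies$target_gene[
    match(colnames(xq$values), sim$antibodies$antibody_id)]) > 0)
  expect_false(any(xq$samples$role %in% c("replicate", "pool")))

  # idempotence
  xq2 <- apply_qc(xq, rep, sim$antibodies)
  expect_equal(xq2$values, xq$values)
})

test_that("target de-duplication keeps the most reproducible antibody", {
  toy <- qc_toy(n_study = 8, n_pairs = 4, p = 2, seed = 3)
  x <- toy$x
  pairs <- replicate_pairs_from_samples(x$samples)
  # AB01 perfectly reproducible, AB02 less so, same target
  x$values[pairs$second, "AB01"] <- x$values[pairs$first, "AB01"]
  x$values[pairs$second, "AB02"] <- x$values[pairs$first, "AB02"] *
    exp(withr::with_seed(4, rnorm(nrow(pairs), 0, 0.2)))
  # large biological spread so neither is flagged
  empty <- setNames(rep(1, 2), colnames(x$values))
  igg <- setNames(rep(1, nrow(x$values)) * exp(seq_len(nrow(x$values)) %% 3),
                  rownames(x$values))
  rep <- compute_qc(x, pairs, igg_profile = igg, empty_profile = empty,
                    thresholds = list(rho_rep = 0.2, rho_igg = 0.99, bg_sd = 3))
  abt <- data.frame(antibody_id = c("AB01", "AB02"), target_gene = "G1")
  xq <- apply_qc(x, rep, abt)
  expect_equal(colnames(xq$values), "AB01")
})

test_that("raising the reproducibility threshold never keeps more antibodies", {
  cfg <- simulation_config(n_cases = 20, n_doubles = 0, n_replicate_pairs = 12,
                           n_antibodies = 60, n_duplicate_targets = 0, seed = 6)
  sim <- generate_mfi(generate_cohort(cfg), cfg)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(thr) {
    rep <- compute_qc(sim$mfi, igg_profile = sim$igg_profile,
                      empty_profile = sim$empty_profile,
                      thresholds = list(rho_rep = thr, rho_igg = 0.5, bg_sd = 3))
    tryCatch(ncol(apply_qc(sim$mfi, rep, sim$antibodies)$values),
             error = function(e) 0L)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})
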