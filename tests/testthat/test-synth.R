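test_that("cohort structure: matched trios, doubles, replicates, pools", {
  cfg <- simulation_config(n_cases = 10, n_doubles = 3, n_replicate_pairs = 2,
                           n_antibodies = 20, n_duplicate_targets = 0, seed = 1)
  co <- generate_cohort(cfg)

  expect_equal(sum(co$role == "study"), 30)
  expect_equal(sum(co$role == "double"), 6)
  expect_equal(sum(co$role == "replicate"), 4)
  n_plates <- length(unique(co$plate_id))
  expect_equal(sum(co$role == "pool"), 4 * n_plates)

  # every match set: exactly one case and two controls, same site, age +/- 2
  sets <- split(co[co$role == "study", ], co$match_set_id[co$role == "study"])
  for (s in sets) {
    expect_equal(sum(s$case_status == "case"), 1)
    expect_equal(sum(s$case_status == "control"), 2)
    expect_equal(length(unique(s$site)), 1)
    expect_equal(length(unique(s$plate_id)), 1)
    expect_true(all(abs(s$age - s$age[s$case_status == "case"]) <= 2))
  }

  # replicate pairs share all covariates; double pairs differ in entry date
  for (sub in unique(co$subject_id[co$role == "replicate"])) {
    pair <- co[co$subject_id == sub, ]
    expect_equal(nrow(pair), 2)
    expect_equal(pair$bmi[1], pair$bmi[2])
    expect_equal(pair$entry_date[1], pair$entry_date[2])
    expect_equal(pair$plate_id[1], pair$plate_id[2])
  }
  for (sub in unique(co$subject_id[co$role == "double"])) {
    pair <- co[co$subject_id == sub, ]
    expect_equal(nrow(pair), 2)
    expect_true(pair$entry_date[1] != pair$entry_date[2])
    expect_equal(pair$plate_id[1], pair$plate_id[2])
  }
  expect_true(all(co$age >= 18 | is.na(co$age)))
  expect_true(all(co$bmi > 0 | is.na(co$bmi)))
  expect_false(anyDuplicated(co$sample_id) > 0)
  # wells unique within plate
  expect_true(all(tapply(co$well_id, co$plate_id,
                         function(w) !anyDuplicated(w))))
})

test_that("generator is deterministic and validates its configuration", {
  expect_error(simulation_config(n_cases = 1, n_doubles = -1), ">= 0")
  expect_error(simulation_config(n_cases = 1, n_planted_archetypes = 0), ">= 1")
  expect_error(simulation_config(n_cases = 1, frac_mht_signature_proteins = 1.5),
               "\\[0, 1\\]")
  expect_error(generate_cohort(simulation_config(n_cases = 0)), "n_cases")

  cfg <- simulation_config(n_cases = 5, n_doubles = 2, n_replicate_pairs = 2,
                           n_antibodies = 30, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  co <- generate_cohort(cfg)
  s1 <- generate_mfi(co, cfg)
  s2 <- generate_mfi(co, cfg)
  expect_identical(s1$mfi$values, s2$mfi$values)
  expect_identical(s1$truth$dilution, s2$truth$dilution)

  cfg_bad <- simulation_config(n_cases = 5, n_antibodies = 10,
                               n_bad_reproducibility = 6, n_igg_correlated = 6,
                               seed = 1)
  expect_error(generate_mfi(co, cfg_bad), "more defective")
})

test_that("degenerate generator with all effects zero gives identical rows", {
  cfg <- simulation_config(n_cases = 5, n_doubles = 2, n_replicate_pairs = 2,
                           n_antibodies = 40, archetype_separation = 0,
                           subject_effect_sd = 0, noise_sd = 0, dilution_sd = 0,
                           plate_effect_sd = 0, double_drift_sd = 0,
                           mht_effect_size = 0,
                           covariate_effect_sizes = c(bmi = 0, age = 0,
                                                      entry_date = 0),
                           n_duplicate_targets = 0, seed = 3)
  sim <- generate_mfi(generate_cohort(cfg), cfg)
  v <- sim$mfi$values
  expect_equal(max(apply(v, 2, function(col) diff(range(col)))), 0)
  expect_equal(unname(v[1, ]), unname(pmax(exp(sim$truth$baseline), 1)))
})

test_that("planted high-background antibodies satisfy the filter formula exactly", {
  cfg <- simulation_config(n_cases = 20, n_doubles = 0, n_replicate_pairs = 3,
                           n_antibodies = 60, n_high_background = 5,
                           n_duplicate_targets = 0, seed = 9)
  sim <- generate_mfi(generate_cohort(cfg), cfg)
  v <- sim$mfi$values
  above <- sim$empty_profile > colMeans(v) + 3 * apply(v, 2, sd)
  expect_equal(sum(above), 5)
  expect_setequal(names(which(above)),
                  sim$antibodies$antibody_id[
                    sim$antibodies$planted_defect == "high_background"])
})

test_that("replicate pairs correlate more than doubles, doubles more than random", {
  deltas <- t(sapply(1:20, function(s) {
    cfg <- simulation_config(n_cases = 10, n_doubles = 6, n_replicate_pairs = 6,
                             n_antibodies = 60, n_duplicate_targets = 0,
                             seed = s)
    co <- generate_cohort(cfg)
    sim <- generate_mfi(co, cfg)
    v <- log(sim$mfi$values)
    pair_cor <- function(a, b) {
      mean(vapply(seq_along(a),
                  function(i) cor(v[a[i], ], v[b[i], ], method = "spearman"),
                  1.0))
    }
    rp <- replicate_pairs_from_samples(co)
    dbl <- co[co$role == "double", ]
    dp <- t(vapply(split(dbl$sample_id, dbl$subject_id), `[`, c("", ""), 1:2))
    study <- co$sample_id[co$role == "study"]
    rnd <- matrix(sample(study, 20), ncol = 2)
    c(rep = pair_cor(rp$first, rp$second),
      dbl = pair_cor(dp[, 1], dp[, 2]),
      rnd = pair_cor(rnd[, 1], rnd[, 2]))
  }))
  expect_gt(mean(deltas[, "rep"]), mean(deltas[, "dbl"]))
  expect_gt(mean(deltas[, "dbl"]), mean(deltas[, "rnd"]))
})

test_that("write_simulation writes all advertised plain-text outputs", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_cases = 5, n_doubles = 2, n_replicate_pairs = 3,
                           n_antibodies = 20, n_duplicate_targets = 2, seed = 2)
  sim <- write_simulation(cfg, dir)
  for (f in c("samples.csv", "mfi.csv", "antibodies.csv", "empty_wells.csv",
              "igg.csv", "truth.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  back <- read_mfi_csv(file.path(dir, "mfi.csv"), file.path(dir, "samples.csv"))
  expect_equal(back$values, sim$mfi$values, tolerance = 1e-12)
})
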