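#' Simulation configuration
#'
#' Parameterizes the synthetic cohort and intensity generator. Defaults mirror
#' the structure of the motivating study: 183 incident cases with two
#' age/site-matched controls each, 30 individuals sampled at two visits
#' ("doubles"), 96 duplicated samples (48 technical replicate pairs), four
#' plasma-pool aliquots per 96-well plate, and ~1000 antibodies of which about
#' a third share a target with another antibody. Intensity effects are planted
#' on the log-MFI scale.
#'
#' @param n_cases number of cases; each receives two matched controls.
#' @param n_doubles number of subjects sampled at two visits.
#' @param n_replicate_pairs number of technical replicate pairs (same draw
#'   assayed twice).
#' @param n_antibodies number of antibody features.
#' @param n_planted_archetypes number of planted archetypes (`k_true`).
#' @param archetype_separation archetype effect scale, in units of the
#'   within-archetype log-MFI spread `sqrt(noise_sd^2 + subject_effect_sd^2)`.
#' @param subject_effect_sd sd of the per-subject, per-antibody biological
#'   variation shared by replicate and double pairs (inter-individual
#'   diversity beyond the archetype structure).
#' @param frac_mht_signature_proteins fraction of antibodies carrying an
#'   MHT-ever signature.
#' @param mht_effect_size absolute log-MFI shift of signature antibodies in
#'   MHT ever-users (random sign per antibody).
#' @param covariate_effect_sizes named vector of absolute log-MFI slopes for
#'   `bmi` (per kg/m2), `age` (per year) and `entry_date` (per day).
#' @param covariate_frac_affected named vector: fraction of antibodies
#'   affected per covariate.
#' @param dilution_sd sd of the per-sample log dilution factor.
#' @param plate_effect_sd sd of the per-plate, per-antibody log offset.
#' @param plate_effect_intensity_slope sd of a per-plate slope multiplying the
#'   standardized antibody baseline (intensity-dependent plate effect; 0 =
#'   constant plate offsets).
#' @param noise_sd residual log-MFI sd.
#' @param double_drift_sd sd of the per-subject biological drift added to the
#'   second visit of double subjects.
#' @param n_bad_reproducibility,n_igg_correlated,n_high_background counts of
#'   deliberately defective antibodies per class.
#' @param bad_rep_noise_sd extra noise sd injected into one member of each
#'   replicate pair at bad-reproducibility antibodies.
#' @param n_duplicate_targets number of antibodies that duplicate the target
#'   (and biology) of another antibody; default keeps the study's proportion.
#' @param dirichlet_alpha concentration of the Dirichlet from which archetype
#'   weights are drawn (0.3 yields both mixtures and near-vertex samples).
#' @param missing_rates named vector of completely-at-random missingness rates
#'   per covariate column.
#' @param seed integer seed; identical configurations produce byte-identical
#'   output.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 183,
                              n_doubles = 30,
                              n_replicate_pairs = 48,
                              n_antibodies = 1073,
                              n_planted_archetypes = 5,
                              archetype_separation = 4,
                              subject_effect_sd = 0.3,
                              frac_mht_signature_proteins = 0.1,
                              mht_effect_size = 0.5,
                              covariate_effect_sizes = c(bmi = 0.02, age = 0.015,
                                                         entry_date = 5e-4),
                              covariate_frac_affected = c(bmi = 0.3, age = 0.4,
                                                          entry_date = 0.05),
                              dilution_sd = 0.2,
                              plate_effect_sd = 0.1,
                              plate_effect_intensity_slope = 0,
                              noise_sd = 0.1,
                              double_drift_sd = 0.3,
                              n_bad_reproducibility = 0,
                              n_igg_correlated = 0,
                              n_high_background = 0,
                              bad_rep_noise_sd = 2,
                              n_duplicate_targets = round(n_antibodies * 372 / 1073),
                              dirichlet_alpha = 0.3,
                              missing_rates = c(bmi = 0.007, menopausal = 0.002,
                                                mht_status = 0.013,
                                                statin_status = 0.32,
                                                dense_area = 0.036,
                                                smoking = 0.005, alcohol = 0.004,
                                                parity = 0.002, prs = 0.05),
                              seed = 1L) {
  cfg <- list(n_cases = n_cases, n_doubles = n_doubles,
              n_replicate_pairs = n_replicate_pairs,
              n_antibodies = n_antibodies,
              n_planted_archetypes = n_planted_archetypes,
              archetype_separation = archetype_separation,
              subject_effect_sd = subject_effect_sd,
              frac_mht_signature_proteins = frac_mht_signature_proteins,
              mht_effect_size = mht_effect_size,
              covariate_effect_sizes = covariate_effect_sizes,
              covariate_frac_affected = covariate_frac_affected,
              dilution_sd = dilution_sd, plate_effect_sd = plate_effect_sd,
              plate_effect_intensity_slope = plate_effect_intensity_slope,
              noise_sd = noise_sd, double_drift_sd = double_drift_sd,
              n_bad_reproducibility = n_bad_reproducibility,
              n_igg_correlated = n_igg_correlated,
              n_high_background = n_high_background,
              bad_rep_noise_sd = bad_rep_noise_sd,
              n_duplicate_targets = n_duplicate_targets,
              dirichlet_alpha = dirichlet_alpha,
              missing_rates = missing_rates, seed = as.integer(seed))
  counts <- c(cfg$n_doubles, cfg$n_replicate_pairs, cfg$n_antibodies,
              cfg$n_bad_reproducibility, cfg$n_igg_correlated,
              cfg$n_high_background, cfg$n_duplicate_targets)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_planted_archetypes < 1) stop("n_planted_archetypes must be >= 1")
  fr <- c(cfg$frac_mht_signature_proteins, cfg$covariate_frac_affected,
          cfg$missing_rates)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  sds <- c(cfg$dilution_sd, cfg$plate_effect_sd, cfg$noise_sd,
           cfg$double_drift_sd, cfg$bad_rep_noise_sd, cfg$subject_effect_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (abs(cfg$seed) >= 2^30) stop("seed must be a small integer")
  req <- c("bmi", "age", "entry_date")
  if (!all(req %in% names(cfg$covariate_effect_sizes)) ||
      !all(req %in% names(cfg$covariate_frac_affected))) {
    stop("covariate effect sizes/fractions must be named bmi, age, entry_date")
  }
  structure(cfg, class = "simulation_config")
}

# entry dates: uniform over a 600-day sampling window
ENTRY_WINDOW_DAYS <- 600L
PLATE_POOLS <- 4L
PLATE_CAPACITY <- 96L

# subject-level clinical covariates (age and site supplied by the matcher)
sample_clinical <- function(n, age, site) {
  menop <- ifelse(runif(n) < stats::plogis((age - 50.5) / 2), "post", "pre")
  mht <- character(n)
  post <- menop == "post"
  mht[post] <- sample(c("never", "before", "current"), sum(post), TRUE,
                      prob = c(0.47, 0.39, 0.14))
  mht[!post] <- sample(c("never", "before", "current"), sum(!post), TRUE,
                       prob = c(0.90, 0.06, 0.04))
  data.frame(
    age = age, site = site,
    bmi = round(rlnorm(n, log(25.2), 0.155), 1),
    entry_date = sample.int(ENTRY_WINDOW_DAYS + 1L, n, TRUE) - 1L,
    menopausal = menop,
    mht_status = mht,
    statin_status = sample(c("never", "before", "current"), n, TRUE,
                           prob = c(0.73, 0.13, 0.14)),
    dense_area = round(rgamma(n, shape = 1.35, scale = 20.3), 1),
    smoking = round(ifelse(runif(n) < 0.45, 0, rexp(n, 1 / 11)), 1),
    alcohol = round(rgamma(n, shape = 0.9, scale = 64), 1),
    parity = sample(c("never", "ever"), n, TRUE, prob = c(0.145, 0.855)),
    prs = round(rnorm(n), 4),
    stringsAsFactors = FALSE)
}

draw_age <- function(n) pmin(pmax(round(rnorm(n, 59.6, 9.3)), 39), 81)

#' Generate a synthetic matched cohort
#'
#' Builds the sample-record table: `n_cases` cases each 1:2 matched to
#' controls of the same site within +/- 2 years of age, `n_doubles` subjects
#' sampled at two visits, `n_replicate_pairs` technical replicate pairs, and
#' four plasma-pool aliquots per 96-well plate. Matched trios, double pairs
#' and replicate pairs are always placed on the same plate.
#'
#' @param config a [simulation_config()].
#' @return data.frame of sample records (one row per sample) with columns
#'   `sample_id`, `subject_id`, `role`, `case_status`, `match_set_id`, the
#'   clinical covariates, `plate_id` and `well_id`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_cases < 1) stop("n_cases must be >= 1")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  nc <- config$n_cases
  sites <- paste0("site_", 1:4)
  site_prob <- c(0.515, 0.042, 0.036, 0.407)

  case_age <- draw_age(nc)
  case_site <- sample(sites, nc, TRUE, prob = site_prob)
  cases <- sample_clinical(nc, case_age, case_site)
  cases$subject_id <- sprintf("case_%03d", seq_len(nc))
  cases$role <- "study"; cases$case_status <- "case"
  cases$match_set_id <- sprintf("set_%03d", seq_len(nc))

  # controls: same site, age within the +/- 2 year matching tolerance
  ctrl_age <- pmax(rep(case_age, each = 2) +
                     sample(-2:2, 2 * nc, TRUE), 18)
  ctrls <- sample_clinical(2 * nc, ctrl_age, rep(case_site, each = 2))
  ctrls$subject_id <- sprintf("ctrl_%03d_%d", rep(seq_len(nc), each = 2), 1:2)
  ctrls$role <- "study"; ctrls$case_status <- "control"
  ctrls$match_set_id <- rep(cases$match_set_id, each = 2)

  records <- rbind(cases, ctrls)

  if (config$n_doubles > 0) {
    nd <- config$n_doubles
    dbl <- sample_clinical(nd, draw_age(nd), sample(sites, nd, TRUE, prob = site_prob))
    dbl$subject_id <- sprintf("double_%03d", seq_len(nd))
    dbl$role <- "double"; dbl$case_status <- "none"; dbl$match_set_id <- NA
    dbl2 <- dbl
    # second visit 10.7 to 19.9 months later
    dbl2$entry_date <- dbl$entry_date + sample(325:605, nd, TRUE)
    records <- rbind(records, dbl, dbl2)
  }
  if (config$n_replicate_pairs > 0) {
    nr <- config$n_replicate_pairs
    rep1 <- sample_clinical(nr, draw_age(nr), sample(sites, nr, TRUE, prob = site_prob))
    rep1$subject_id <- sprintf("repl_%03d", seq_len(nr))
    rep1$role <- "replicate"; rep1$case_status <- "none"; rep1$match_set_id <- NA
    records <- rbind(records, rep1, rep1)
  }

  # completely-at-random missingness, shared within a subject
  mr <- config$missing_rates
  subj <- unique(records$subject_id)
  for (col in intersect(names(mr), names(records))) {
    if (mr[[col]] <= 0) next
    hit <- subj[runif(length(subj)) < mr[[col]]]
    records[[col]][records$subject_id %in% hit] <- NA
  }

  # plate assignment: trios and pairs stay together, 4 pool wells reserved
  units <- c(split(which(records$match_set_id %in% cases$match_set_id),
                   records$match_set_id[records$match_set_id %in% cases$match_set_id]),
             split(which(records$role %in% c("double", "replicate")),
                   records$subject_id[records$role %in% c("double", "replicate")]))
  units <- units[sample(length(units))]
  cap <- PLATE_CAPACITY - PLATE_POOLS
  plate_no <- integer(nrow(records))
  cur_plate <- 1L; used <- 0L
  for (u in units) {
    if (used + length(u) > cap) { cur_plate <- cur_plate + 1L; used <- 0L }
    plate_no[u] <- cur_plate
    used <- used + length(u)
  }
  records$plate_id <- sprintf("plate_%02d", plate_no)

  n_plates <- max(plate_no)
  pools <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    d <- sample_clinical(PLATE_POOLS, rep(60L, PLATE_POOLS),
                         rep(sites[1], PLATE_POOLS))
    d[] <- lapply(d, function(x) { x[] <- NA; x })
    d$subject_id <- "pool"
    d$role <- "pool"; d$case_status <- "none"; d$match_set_id <- NA
    d$plate_id <- sprintf("plate_%02d", p)
    d
  }))
  records <- rbind(records, pools)

  # deterministic ordering and well layout per plate
  records <- records[order(records$plate_id,
                           records$role != "pool", records$subject_id), ]
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  records$well_id <- wells[stats::ave(seq_len(nrow(records)), records$plate_id,
                                      FUN = seq_along)]
  records$sample_id <- sprintf("S%04d", seq_len(nrow(records)))
  rownames(records) <- NULL
  cols <- c("sample_id", "subject_id", "role", "case_status", "match_set_id",
            "age", "bmi", "entry_date", "site", "menopausal", "mht_status",
            "statin_status", "dense_area", "smoking", "alcohol", "parity",
            "prs", "plate_id", "well_id")
  records[, cols]
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate a synthetic MFI matrix with known truth
#'
#' Plants, on the log-MFI scale, per-antibody baselines, archetype structure
#' (sample weights drawn from a Dirichlet), linear covariate effects, an
#' MHT-ever signature, per-plate batch effects, per-sample dilution factors,
#' residual noise, and three classes of deliberately defective antibodies.
#' Replicate pairs differ only in technical terms; double pairs additionally
#' carry a per-subject biological drift at the second visit.
#'
#' @param cohort sample records from [generate_cohort()].
#' @param config the [simulation_config()] used to generate the cohort.
#' @return list with elements `mfi` (an [mfi_matrix()]), `antibodies`
#'   (antibody metadata: id, target gene, array, planted defect),
#'   `empty_profile` (per-antibody buffer-well MFI), `igg_profile`
#'   (per-sample IgG level), and `truth` (all planted parameters).
#' @export
generate_mfi <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("cohort is empty")
  ndef <- config$n_bad_reproducibility + config$n_igg_correlated +
    config$n_high_background
  if (ndef > config$n_antibodies) {
    stop("more defective antibodies requested than n_antibodies")
  }
  with_seed(config$seed + 500009L, generate_mfi_impl(cohort, config))
}

generate_mfi_impl <- function(cohort, config) {
  n <- nrow(cohort)
  p <- config$n_antibodies
  k <- config$n_planted_archetypes
  ab_ids <- sprintf("AB_%04d", seq_len(p))

  # target map: the last n_duplicate_targets antibodies re-use earlier targets
  n_dup <- min(config$n_duplicate_targets, p - 1)
  n_unique <- p - n_dup
  target <- sprintf("GENE_%04d", seq_len(n_unique))
  dup_of <- integer(0)
  if (n_dup > 0) {
    dup_of <- sample(n_unique, n_dup, replace = n_dup > n_unique)
    target <- c(target, target[dup_of])
  }
  src_col <- c(seq_len(n_unique), dup_of)   # biology source per antibody

  baseline <- rnorm(p, 6.5, 0.8)
  # separation is relative to the within-archetype spread
  within_sd <- sqrt(config$noise_sd^2 + config$subject_effect_sd^2)
  arch_scale <- config$archetype_separation * within_sd
  A_unique <- matrix(rnorm(k * n_unique, 0, arch_scale), nrow = k)
  A <- A_unique[, src_col, drop = FALSE]
  colnames(A) <- ab_ids

  # subject-level archetype weights (pools share one fixed profile)
  subj <- unique(cohort$subject_id[cohort$role != "pool"])
  alpha_subj <- rdirichlet(length(subj), rep(config$dirichlet_alpha, k))
  rownames(alpha_subj) <- subj
  alpha <- matrix(1 / k, nrow = n, ncol = k,
                  dimnames = list(cohort$sample_id, paste0("arch_", seq_len(k))))
  not_pool <- cohort$role != "pool"
  alpha[not_pool, ] <- alpha_subj[cohort$subject_id[not_pool], , drop = FALSE]

  # per-subject biological variation (shared by replicate/double pairs and by
  # antibodies with the same target)
  all_subj <- unique(cohort$subject_id)
  U_subj <- matrix(rnorm(length(all_subj) * n_unique, 0, config$subject_effect_sd),
                   nrow = length(all_subj), dimnames = list(all_subj, NULL))
  subj_term <- U_subj[cohort$subject_id, src_col, drop = FALSE]

  # covariate effects on centered covariates; missing covariate = no deviation
  covars <- c("bmi", "age", "entry_date")
  slopes <- matrix(0, nrow = p, ncol = 3, dimnames = list(ab_ids, covars))
  affected <- list()
  for (cv in covars) {
    n_aff <- round(config$covariate_frac_affected[[cv]] * n_unique)
    idx_u <- sample(n_unique, n_aff)
    sl_u <- numeric(n_unique)
    sl_u[idx_u] <- config$covariate_effect_sizes[[cv]] *
      sample(c(-1, 1), n_aff, TRUE)
    slopes[, cv] <- sl_u[src_col]
    affected[[cv]] <- ab_ids[slopes[, cv] != 0]
  }
  cov_vals <- sapply(covars, function(cv) {
    x <- cohort[[cv]]
    mu <- mean(x[cohort$role == "study"], na.rm = TRUE)
    ifelse(is.na(x), 0, x - mu)
  })
  cov_term <- cov_vals %*% t(slopes)

  # MHT-ever signature
  n_sig <- round(config$frac_mht_signature_proteins * n_unique)
  mht_u <- numeric(n_unique)
  if (n_sig > 0) {
    mht_u[sample(n_unique, n_sig)] <- config$mht_effect_size *
      sample(c(-1, 1), n_sig, TRUE)
  }
  mht_effect <- mht_u[src_col]
  mht_ever <- !is.na(cohort$mht_status) & cohort$mht_status %in% c("before", "current")
  mht_term <- outer(as.numeric(mht_ever), mht_effect)

  # plate effects (optionally intensity-dependent), dilution, drift, noise
  plates <- sort(unique(cohort$plate_id))
  b_std <- as.numeric(scale(baseline))
  plate_eff <- matrix(rnorm(length(plates) * p, 0, config$plate_effect_sd),
                      nrow = length(plates), dimnames = list(plates, ab_ids))
  if (config$plate_effect_intensity_slope > 0) {
    pslope <- rnorm(length(plates), 0, config$plate_effect_intensity_slope)
    plate_eff <- plate_eff + outer(pslope, b_std)
  }
  dilution <- rnorm(n, 0, config$dilution_sd)
  names(dilution) <- cohort$sample_id

  drift <- matrix(0, n, p)
  dbl_subj <- unique(cohort$subject_id[cohort$role == "double"])
  drift_by_subj <- list()
  for (s in dbl_subj) {
    ix <- which(cohort$subject_id == s)
    second <- ix[which.max(cohort$entry_date[ix])]
    d <- rnorm(p, 0, config$double_drift_sd)
    drift[second, ] <- d
    drift_by_subj[[s]] <- d
  }

  eps <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)

  # defective antibodies (classes sampled disjointly)
  def_pool <- sample(p)
  take <- function(m) { out <- def_pool[seq_len(m)]; def_pool <<- def_pool[-seq_len(m)]; out }
  bad_rep <- if (config$n_bad_reproducibility > 0) take(config$n_bad_reproducibility) else integer(0)
  igg_cor <- if (config$n_igg_correlated > 0) take(config$n_igg_correlated) else integer(0)
  high_bg <- if (config$n_high_background > 0) take(config$n_high_background) else integer(0)

  # one member of each replicate pair gets inflated noise at bad-rep antibodies
  if (length(bad_rep) > 0 && any(cohort$role == "replicate")) {
    rsub <- unique(cohort$subject_id[cohort$role == "replicate"])
    second_member <- vapply(rsub, function(s) which(cohort$subject_id == s)[2], 1L)
    eps[second_member, bad_rep] <- eps[second_member, bad_rep] +
      rnorm(length(second_member) * length(bad_rep), 0, config$bad_rep_noise_sd)
  }

  igg_g <- rnorm(n)
  igg_profile <- exp(5 + 0.8 * igg_g)
  names(igg_profile) <- cohort$sample_id
  igg_term <- matrix(0, n, p)
  if (length(igg_cor) > 0) igg_term[, igg_cor] <- igg_g  # lambda = 1

  log_mfi <- matrix(baseline, n, p, byrow = TRUE) + alpha %*% A + subj_term +
    cov_term + mht_term + plate_eff[cohort$plate_id, , drop = FALSE] +
    dilution + drift + igg_term + eps
  values <- pmax(exp(log_mfi), 1.0)
  dimnames(values) <- list(cohort$sample_id, ab_ids)

  # buffer wells: planted high-background antibodies exceed mean + 3 sd of
  # sample MFI by construction; the rest sit far below
  smean <- colMeans(values)
  ssd <- apply(values, 2, sd)
  empty_profile <- exp(baseline - 2 + rnorm(p, 0, 0.1))
  empty_profile[high_bg] <- smean[high_bg] + 4 * ssd[high_bg]
  names(empty_profile) <- ab_ids

  defect <- rep("none", p)
  defect[bad_rep] <- "bad_reproducibility"
  defect[igg_cor] <- "igg_correlated"
  defect[high_bg] <- "high_background"
  antibodies <- data.frame(
    antibody_id = ab_ids, target_gene = target,
    array_id = paste0("SBA", rep_len(1:3, p)),
    planted_defect = defect, stringsAsFactors = FALSE)

  truth <- list(
    config = unclass(config), baseline = setNames(baseline, ab_ids),
    archetypes = A, alpha = alpha,
    covariate_slopes = slopes, covariate_affected = affected,
    mht_effect = setNames(mht_effect, ab_ids),
    mht_ever = setNames(mht_ever, cohort$sample_id),
    plate_effects = plate_eff, dilution = dilution,
    double_drift = drift_by_subj,
    defects = antibodies[antibodies$planted_defect != "none",
                         c("antibody_id", "planted_defect")],
    duplicate_map = if (n_dup > 0)
      data.frame(antibody_id = ab_ids[n_unique + seq_len(n_dup)],
                 duplicates = ab_ids[dup_of]) else NULL)

  list(mfi = mfi_matrix(values, cohort), antibodies = antibodies,
       empty_profile = empty_profile, igg_profile = igg_profile, truth = truth)
}

#' Run the generator and write all outputs as plain text
#'
#' Writes `samples.csv`, `mfi.csv`, `antibodies.csv`, `empty_wells.csv`,
#' `igg.csv` and `truth.json` into `dir`.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the generator output of [generate_mfi()] plus `cohort`.
#' @export
write_simulation <- function(config, dir) {
  cohort <- generate_cohort(config)
  sim <- generate_mfi(cohort, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort, file.path(dir, "samples.csv"), row.names = FALSE)
  write_mfi_csv(sim$mfi, file.path(dir, "mfi.csv"))
  write.csv(sim$antibodies, file.path(dir, "antibodies.csv"), row.names = FALSE)
  write.csv(data.frame(antibody_id = names(sim$empty_profile),
                       empty_mfi = sim$empty_profile),
            file.path(dir, "empty_wells.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = names(sim$igg_profile),
                       igg_mfi = sim$igg_profile),
            file.path(dir, "igg.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$archetypes <- as.data.frame(truth$archetypes)
  truth$alpha <- as.data.frame(truth$alpha)
  truth$covariate_slopes <- as.data.frame(truth$covariate_slopes)
  truth$plate_effects <- as.data.frame(truth$plate_effects)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  sim$cohort <- cohort
  invisible(sim)
}
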