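#' Default pipeline configuration
#'
#' Nested list of all stage parameters and toggles. The configuration
#' round-trips losslessly through YAML or JSON; unknown keys are rejected by
#' the validator. Per-stage seeds are derived deterministically from the
#' master `seed` so stages can be rerun in isolation.
#'
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = "pipeline_out",
    stages = list(simulate = TRUE, normalize = TRUE, qc = TRUE, adjust = TRUE,
                  cluster = TRUE, stability = TRUE, characterize = TRUE,
                  casecontrol = TRUE),
    simulate = list(n_cases = 60, n_doubles = 10, n_replicate_pairs = 10,
                    n_antibodies = 200, n_planted_archetypes = 3,
                    archetype_separation = 4, noise_sd = 0.1,
                    dilution_sd = 0.2, plate_effect_sd = 0.1,
                    n_bad_reproducibility = 5, n_igg_correlated = 5,
                    n_high_background = 5, n_duplicate_targets = 10),
    normalize = list(abs_pqn_n_similar = 50, ma_span = 0.3),
    qc = list(rho_rep = 0.7, rho_igg = 0.5, bg_sd = 3),
    adjust = list(covars = c("bmi", "age", "entry_date")),
    cluster = list(k_min = 2, k_max = 8, restarts = 5),
    stability = list(B = 150, n_random_pairs = 50),
    characterize = list(target_cluster = NA, shortlist_m = 25),
    casecontrol = list(models = c(1, 2, 3))
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks the structure against [default_pipeline_config()]: unknown keys at
#' either level are rejected, all violations reported at once. Missing keys
#' fall back to the defaults.
#'
#' @param config a (possibly partial) configuration list, or a path to a
#'   YAML/JSON file.
#' @return the completed, validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  ref <- default_pipeline_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    errs <- c(errs, paste("unknown top-level key(s):",
                          paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(ref))) {
    if (is.list(ref[[sec]]) && !is.null(names(ref[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(bad)) {
        errs <- c(errs, sprintf("unknown key(s) in '%s': %s", sec,
                                paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  out <- ref
  for (sec in names(config)) {
    if (is.list(ref[[sec]]) && !is.null(names(ref[[sec]]))) {
      for (kk in names(config[[sec]])) out[[sec]][[kk]] <- config[[sec]][[kk]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  out$seed <- as.integer(out$seed)
  out
}

stage_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) * 7919 + 104729 * stage_index) %% 2^30)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, normalize, qc, adjust,
#' cluster, stability, characterize, casecontrol), writes per-stage CSV/JSON
#' outputs into `config$out_dir`, and returns a run manifest with seeds and
#' per-stage dimensions. Any stage failure aborts with a stage-named error.
#'
#' @param config a `pipeline_config`, partial list, or YAML/JSON path (see
#'   [validate_pipeline_config()]).
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("plasmarch")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(...), seed = stage_seed(config$seed,
                                                                match(stage, names(config$stages))))
  }
  run_stage <- function(stage, expr) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  env <- new.env(parent = emptyenv())

  run_stage("simulate", {
    sc <- do.call(simulation_config,
                  c(config$simulate, list(seed = stage_seed(config$seed, 1))))
    sim <- write_simulation(sc, config$out_dir)
    env$sim <- sim
    note("simulate", n_samples = nrow(sim$cohort),
         n_antibodies = ncol(sim$mfi$values))
  })

  run_stage("normalize", {
    x <- abs_pqn(env$sim$mfi, n_similar = config$normalize$abs_pqn_n_similar)
    x <- ma_normalize(x, span = config$normalize$ma_span)
    env$norm <- x
    write_mfi_csv(x, file.path(config$out_dir, "mfi_norm.csv"))
    note("normalize", dim = dim(x$values))
  })

  run_stage("qc", {
    rep <- compute_qc(env$norm, igg_profile = env$sim$igg_profile,
                      empty_profile = env$sim$empty_profile,
                      thresholds = list(rho_rep = config$qc$rho_rep,
                                        rho_igg = config$qc$rho_igg,
                                        bg_sd = config$qc$bg_sd))
    env$qc_report <- rep
    env$qc <- apply_qc(env$norm, rep, env$sim$antibodies)
    write.csv(rep, file.path(config$out_dir, "qc_report.csv"), row.names = FALSE)
    write_mfi_csv(env$qc, file.path(config$out_dir, "mfi_qc.csv"))
    note("qc", n_flagged = sum(rep$flagged), dim = dim(env$qc$values))
  })

  run_stage("adjust", {
    env$scan <- covariate_scan(env$qc, covars = config$adjust$covars)
    env$adj <- residualize(env$qc, covars = config$adjust$covars)
    write.csv(data.frame(antibody_id = rownames(env$scan$pvalues),
                         env$scan$pvalues),
              file.path(config$out_dir, "scan.csv"), row.names = FALSE)
    write_mfi_csv(env$adj, file.path(config$out_dir, "mfi_adj.csv"))
    note("adjust", counts = as.list(env$scan$counts), dim = dim(env$adj$values))
  })

  run_stage("cluster", {
    study <- env$adj$samples$role == "study"
    Xs <- env$adj$values[study, , drop = FALSE]
    sel <- select_k(Xs, k_range = config$cluster$k_min:config$cluster$k_max,
                    restarts = config$cluster$restarts,
                    seed = stage_seed(config$seed, 5))
    env$model <- sel$models[[match(sel$k_opt, sel$k_range)]]
    cl <- assign_clusters(env$model)
    held <- env$adj$values[!study, , drop = FALSE]
    if (nrow(held)) {
      cl_held <- assign_clusters(predict_coefficients(env$model, held))
      cl <- rbind(cl, cl_held)
    }
    env$clusters <- cl
    write.csv(cl, file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
    note("cluster", k_opt = sel$k_opt, rss = sel$rss,
         sizes = as.list(table(cl$cluster[match(rownames(Xs), cl$sample_id)])))
  })

  run_stage("stability", {
    study <- env$adj$samples$role == "study"
    st <- bootstrap_mji(env$adj$values[study, , drop = FALSE],
                        ref_model = env$model, B = config$stability$B,
                        seed = stage_seed(config$seed, 6))
    labels <- setNames(env$clusters$cluster, env$clusters$sample_id)
    s <- env$adj$samples
    rp <- replicate_pairs_from_samples(env$sim$cohort)
    rp <- rp[rp$first %in% names(labels) & rp$second %in% names(labels), ]
    dbl <- s[s$role == "double", ]
    dp <- do.call(rbind, lapply(split(dbl$sample_id, dbl$subject_id), function(id)
      if (length(id) == 2) data.frame(first = id[1], second = id[2])))
    conc <- NULL
    if (nrow(rp) > 0 && !is.null(dp) && nrow(dp) > 0) {
      conc <- pair_concordance(labels, rp, dp,
                               study_ids = s$sample_id[study],
                               n_random_pairs = min(config$stability$n_random_pairs,
                                                    floor(sum(study) / 2)),
                               seed = stage_seed(config$seed, 6) + 1L)
    }
    env$stability <- st
    jsonlite::write_json(list(mji_mean = st$mji_mean, mji_sd = st$mji_sd,
                              B = st$B,
                              concordance = if (!is.null(conc))
                                list(rate = as.list(conc$rate),
                                     fisher_p = as.list(conc$fisher_p))),
                         file.path(config$out_dir, "stability.json"),
                         digits = NA, auto_unbox = TRUE)
    note("stability", B = st$B, mji = st$mji_mean)
  })

  run_stage("characterize", {
    study <- env$adj$samples$role != "replicate"
    s <- env$adj$samples[study, ]
    labels <- env$clusters$cluster[match(s$sample_id, env$clusters$sample_id)]
    target <- config$characterize$target_cluster
    if (is.na(target)) {
      target <- as.integer(names(which.max(table(
        labels[s$case_status == "case"]) / table(labels))))
    }
    da <- differential_abundance(
      env$adj$values[study, , drop = FALSE], labels, target,
      x_linear = env$qc$values[match(s$sample_id, rownames(env$qc$values)), ,
                               drop = FALSE])
    sl <- shortlist(da, m = config$characterize$shortlist_m)
    clin <- cluster_clinical_tests(s, labels)
    assoc <- trait_association(env$adj$values[study, , drop = FALSE],
                               unique(unlist(sl)), s)
    write.csv(da, file.path(config$out_dir, "differential.csv"), row.names = FALSE)
    jsonlite::write_json(sl, file.path(config$out_dir, "shortlist.json"))
    write.csv(clin, file.path(config$out_dir, "clinical_tests.csv"),
              row.names = FALSE)
    write.csv(assoc, file.path(config$out_dir, "associations.csv"),
              row.names = FALSE)
    note("characterize", target_cluster = target,
         n_fdr_significant = sum(da$fdr < 0.05),
         shortlist_sizes = lapply(sl, length))
  })

  run_stage("casecontrol", {
    scr <- screen_proteins_clogit(env$qc, mfi_samples(env$qc),
                                  models = config$casecontrol$models)
    write.csv(scr$table, file.path(config$out_dir, "clogit.csv"),
              row.names = FALSE)
    note("casecontrol", summary = split(scr$summary, seq_len(nrow(scr$summary))))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}
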