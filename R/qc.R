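#' Derive replicate pairs from the sample table
#'
#' @param samples sample-record data.frame.
#' @return data.frame with columns `first` and `second` (sample ids), one row
#'   per technical replicate pair.
#' @export
replicate_pairs_from_samples <- function(samples) {
  rep_s <- samples[samples$role == "replicate", , drop = FALSE]
  if (nrow(rep_s) == 0) return(data.frame(first = character(), second = character()))
  sp <- split(rep_s$sample_id, rep_s$subject_id)
  sp <- sp[vapply(sp, length, 1L) == 2]
  data.frame(first = vapply(sp, `[`, "", 1), second = vapply(sp, `[`, "", 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-antibody quality-control statistics and exclusion flags
#'
#' Computes, per antibody: the Spearman correlation between the members of
#' technical replicate pairs (`replicate_rho`), the Spearman correlation with
#' the per-sample IgG level across study samples (`igg_rho`), and background
#' statistics from sample-free buffer wells. Antibodies are flagged when
#' `replicate_rho < rho_rep` (low reproducibility), `igg_rho > rho_igg`
#' (IgG-correlated), or `empty > mean + bg_sd * sd` of study-sample MFI
#' (elevated background).
#'
#' @param x an [mfi_matrix()].
#' @param replicate_pairs data.frame with `first`/`second` sample-id columns;
#'   defaults to pairs derived from the sample table.
#' @param igg_profile named per-sample IgG level (names = sample ids).
#' @param empty_profile named per-antibody buffer-well MFI.
#' @param thresholds list with `rho_rep`, `rho_igg`, `bg_sd`.
#' @return a `qc_report` data.frame (one row per antibody) with the
#'   statistics and logical flag columns; thresholds kept as an attribute.
#' @export
compute_qc <- function(x,
                       replicate_pairs = replicate_pairs_from_samples(mfi_samples(x)),
                       igg_profile, empty_profile,
                       thresholds = list(rho_rep = 0.7, rho_igg = 0.5, bg_sd = 3)) {
  stopifnot(inherits(x, "mfi_matrix"))
  v <- x$values
  ab_ids <- colnames(v)
  if (nrow(replicate_pairs) < 3) stop("need at least 3 replicate pairs")
  if (!all(c(replicate_pairs$first, replicate_pairs$second) %in% rownames(v))) {
    stop("replicate pair sample ids missing from the matrix")
  }
  if (is.null(names(empty_profile)) || !setequal(names(empty_profile), ab_ids)) {
    stop("empty_profile must be named by the matrix antibody ids")
  }
  study <- x$samples$sample_id[x$samples$role == "study"]
  if (length(study) == 0) study <- rownames(v)
  if (is.null(names(igg_profile)) || !all(study %in% names(igg_profile))) {
    stop("igg_profile must be named by sample ids and cover study samples")
  }

  v1 <- v[replicate_pairs$first, , drop = FALSE]
  v2 <- v[replicate_pairs$second, , drop = FALSE]
  rep_rho <- vapply(seq_along(ab_ids), function(j)
    suppressWarnings(cor(v1[, j], v2[, j], method = "spearman")), 1.0)

  vs <- v[study, , drop = FALSE]
  igg <- igg_profile[study]
  igg_rho <- suppressWarnings(as.numeric(cor(vs, igg, method = "spearman")))

  smean <- colMeans(vs)
  ssd <- apply(vs, 2, sd)
  empty <- as.numeric(empty_profile[ab_ids])

  rep_rho[!is.finite(rep_rho)] <- 0
  igg_rho[!is.finite(igg_rho)] <- 0
  report <- data.frame(
    antibody_id = ab_ids,
    replicate_rho = rep_rho,
    igg_rho = igg_rho,
    empty_mfi = empty,
    sample_mean_mfi = smean,
    sample_sd_mfi = ssd,
    low_reproducibility = rep_rho < thresholds$rho_rep,
    igg_correlated = igg_rho > thresholds$rho_igg,
    high_background = empty > smean + thresholds$bg_sd * ssd,
    row.names = NULL, stringsAsFactors = FALSE)
  report$flagged <- report$low_reproducibility | report$igg_correlated |
    report$high_background
  attr(report, "thresholds") <- thresholds
  class(report) <- c("qc_report", class(report))
  report
}

#' Apply antibody and sample exclusions
#'
#' Drops flagged antibodies, de-duplicates antibodies sharing a target gene
#' (keeping the one with the highest replicate correlation, ties broken by
#' antibody id), and removes technical replicate (and, by default, pool)
#' samples.
#'
#' @param x the [mfi_matrix()] on which `report` was computed.
#' @param report a `qc_report` from [compute_qc()].
#' @param antibody_table data.frame with `antibody_id` and `target_gene`.
#' @param drop_replicates,drop_pools drop samples with these roles.
#' @param require_covariates optional character vector; samples missing any of
#'   these covariates are dropped.
#' @return the filtered [mfi_matrix()] with one antibody per target.
#' @export
apply_qc <- function(x, report, antibody_table,
                     drop_replicates = TRUE, drop_pools = TRUE,
                     require_covariates = NULL) {
  stopifnot(inherits(x, "mfi_matrix"), inherits(report, "qc_report"))
  ab_ids <- colnames(x$values)
  if (!all(ab_ids %in% report$antibody_id)) {
    stop("report does not cover all antibodies in the matrix")
  }
  report <- report[match(ab_ids, report$antibody_id), ]
  keep <- !report$flagged
  if (!any(keep)) stop("no antibodies survive QC")

  tg <- antibody_table$target_gene[match(ab_ids, antibody_table$antibody_id)]
  if (anyNA(tg)) stop("antibody_table does not cover all antibodies")
  surv <- data.frame(j = which(keep), ab = ab_ids[keep], tg = tg[keep],
                     rho = report$replicate_rho[keep])
  # keep-rule: highest replicate correlation, ties by antibody id
  surv <- surv[order(surv$tg, -surv$rho, surv$ab), ]
  surv <- surv[!duplicated(surv$tg), ]
  keep_j <- sort(surv$j)

  roles <- x$samples$role
  keep_i <- rep(TRUE, nrow(x$values))
  if (drop_replicates) keep_i <- keep_i & roles != "replicate"
  if (drop_pools) keep_i <- keep_i & roles != "pool"
  if (!is.null(require_covariates)) {
    cc <- complete.cases(x$samples[, require_covariates, drop = FALSE])
    keep_i <- keep_i & cc
  }
  mfi_subset(x, which(keep_i), keep_j)
}
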