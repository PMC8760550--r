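#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided p-value for independence in an r x c table of counts. 2 x 2
#' tables use the exact hypergeometric sum; larger tables use the exact
#' network algorithm when the table is small enough, otherwise seeded Monte
#' Carlo over tables with fixed margins ordered by conditional probability.
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @param method `"exact"` or `"montecarlo"`.
#' @param mc_draws Monte Carlo table draws.
#' @param seed integer seed for the Monte Carlo path.
#' @return list with `p`, the `method` actually used, and `mc_draws` when
#'   Monte Carlo was used.
#' @export
fisher_exact_rxc <- function(table, method = c("exact", "montecarlo"),
                             mc_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has a zero-margin row or column")
  }
  if (method == "exact") {
    ft <- fisher.test(table, workspace = 2e7)
    list(p = ft$p.value, method = "exact")
  } else {
    ft <- with_seed(seed, fisher.test(table, simulate.p.value = TRUE,
                                      B = as.integer(mc_draws)))
    list(p = ft$p.value, method = "montecarlo", mc_draws = as.integer(mc_draws))
  }
}

# cross-tabulate a categorical variable against a two-group split,
# excluding missing values
two_group_table <- function(values, in_group) {
  keep <- !is.na(values)
  tab <- table(factor(values[keep]), factor(in_group[keep], levels = c(TRUE, FALSE)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
    stop("variable is constant or a group is empty after removing missing values")
  }
  tab
}

#' Clinical comparisons across clusters
#'
#' For each variable: continuous variables are compared with two-sided
#' Wilcoxon rank-sum tests (each cluster vs the rest, and all cluster pairs);
#' categorical variables with Fisher's exact test on the cross-tabulation
#' (missing values excluded). Polygenic scores are continuous, hence
#' Wilcoxon.
#'
#' @param annotations sample annotation data.frame (one row per sample).
#' @param labels integer cluster label per row of `annotations`.
#' @param variables named character vector mapping variable name to type
#'   (`"continuous"` or `"categorical"`); defaults cover the standard
#'   clinical set.
#' @return data.frame with one row per (variable, scope) comparison: the
#'   test used, scope (`cluster k vs rest` or `cluster i vs j`), and the
#'   two-sided p-value.
#' @export
cluster_clinical_tests <- function(annotations, labels,
                                   variables = c(age = "continuous",
                                                 bmi = "continuous",
                                                 dense_area = "continuous",
                                                 smoking = "continuous",
                                                 alcohol = "continuous",
                                                 prs = "continuous",
                                                 case_status = "categorical",
                                                 menopausal = "categorical",
                                                 mht_status = "categorical",
                                                 statin_status = "categorical",
                                                 parity = "categorical")) {
  stopifnot(nrow(annotations) == length(labels))
  ks <- sort(unique(labels))
  res <- list()
  add <- function(var, test, scope, p) {
    res[[length(res) + 1]] <<- data.frame(variable = var, test = test,
                                          scope = scope, p = p,
                                          stringsAsFactors = FALSE)
  }
  scopes <- c(lapply(ks, function(k) list(name = sprintf("cluster %d vs rest", k),
                                          a = labels == k, b = labels != k)),
              unlist(lapply(ks, function(i) lapply(ks[ks > i], function(j) {
                list(name = sprintf("cluster %d vs %d", i, j),
                     a = labels == i, b = labels == j)
              })), recursive = FALSE))
  for (var in names(variables)) {
    x <- annotations[[var]]
    if (is.null(x)) stop("annotation column not found: ", var)
    for (sc in scopes) {
      if (variables[[var]] == "continuous") {
        xa <- x[sc$a]; xb <- x[sc$b]
        if (var == "prs") { xa <- abs(xa); xb <- abs(xb) }
        p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
        add(var, "wilcoxon", sc$name, p)
      } else {
        use <- sc$a | sc$b
        tab <- two_group_table(x[use], sc$a[use])
        add(var, "fisher", sc$name, fisher_exact_rxc(tab)$p)
      }
    }
  }
  do.call(rbind, res)
}

#' Differential protein abundance, cluster vs rest
#'
#' Per antibody: Welch two-sample t-test of the cluster members against all
#' other samples on (log-scale) adjusted values, Benjamini-Hochberg
#' adjustment across antibodies, and optionally the signed median fold
#' change on a linear-scale matrix.
#'
#' @param x_adj log-scale matrix (samples x antibodies) or log-scale
#'   [mfi_matrix()].
#' @param labels cluster label per sample.
#' @param cluster_id the cluster compared against the rest.
#' @param x_linear optional positive linear-scale matrix (same layout) for
#'   the fold change; typically the normalized, pre-adjustment MFI.
#' @return a `differential_result` data.frame: `mean_diff` (cluster minus
#'   rest, log scale), `t_stat`, `p`, `fdr`, `direction`, and `fc_signed`
#'   when `x_linear` is given.
#' @export
differential_abundance <- function(x_adj, labels, cluster_id, x_linear = NULL) {
  v <- if (inherits(x_adj, "mfi_matrix")) log_values(x_adj) else as.matrix(x_adj)
  stopifnot(length(labels) == nrow(v))
  in_cl <- labels == cluster_id
  n1 <- sum(in_cl); n2 <- sum(!in_cl)
  if (n1 < 3 || n2 < 3) stop("cluster and rest must both have >= 3 samples")

  m1 <- colMeans(v[in_cl, , drop = FALSE])
  m2 <- colMeans(v[!in_cl, , drop = FALSE])
  v1 <- apply(v[in_cl, , drop = FALSE], 2, var)
  v2 <- apply(v[!in_cl, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  res <- data.frame(antibody_id = colnames(v), mean_diff = m1 - m2,
                    t_stat = tstat, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    direction = ifelse(m1 >= m2, "higher_in_cluster",
                                       "lower_in_cluster"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(x_linear)) {
    fc <- median_fold_change(x_linear, labels, cluster_id)
    res$fc_signed <- fc[res$antibody_id]
  }
  class(res) <- c("differential_result", class(res))
  res
}

#' Shortlist cluster-defining proteins
#'
#' Within each direction (higher / lower in the cluster), returns the union
#' of the `m` antibodies with the lowest p-values and the `m` with the
#' largest absolute mean difference, so each set has between `m` and `2m`
#' members (fewer, with a warning, if a direction has fewer than `m`
#' antibodies).
#'
#' @param result a `differential_result`.
#' @param m per-criterion list length.
#' @return list with character vectors `higher` and `lower`.
#' @export
shortlist <- function(result, m = 25) {
  stopifnot(inherits(result, "differential_result"))
  pick <- function(dir) {
    d <- result[result$direction == dir, ]
    if (nrow(d) < m) {
      warning("direction ", dir, " has fewer than ", m,
              " antibodies; returning all")
      return(d$antibody_id)
    }
    by_p <- d$antibody_id[order(d$p, d$antibody_id)][seq_len(m)]
    by_diff <- d$antibody_id[order(-abs(d$mean_diff), d$antibody_id)][seq_len(m)]
    union(by_p, by_diff)
  }
  list(higher = pick("higher_in_cluster"), lower = pick("lower_in_cluster"))
}

#' Signed median fold change, cluster vs rest
#'
#' Ratio of the cluster median to the rest median on the linear scale,
#' sign-coded: `r` when `r >= 1`, `-1/r` otherwise, so a value of -2 means
#' the cluster median is half the rest.
#'
#' @param x positive linear-scale matrix or linear [mfi_matrix()].
#' @param labels cluster label per sample.
#' @param cluster_id the cluster of interest.
#' @return named vector of signed fold changes per antibody.
#' @export
median_fold_change <- function(x, labels, cluster_id) {
  v <- if (inherits(x, "mfi_matrix")) x$values else as.matrix(x)
  stopifnot(length(labels) == nrow(v))
  if (any(v <= 0)) stop("fold change requires positive linear-scale values")
  in_cl <- labels == cluster_id
  med1 <- apply(v[in_cl, , drop = FALSE], 2, median)
  med2 <- apply(v[!in_cl, , drop = FALSE], 2, median)
  if (any(med1 <= 0) || any(med2 <= 0)) stop("non-positive group median")
  r <- med1 / med2
  setNames(ifelse(r >= 1, r, -1 / r), colnames(v))
}

#' Associate shortlisted proteins with clinical traits
#'
#' Per shortlisted protein: linear regression of BMI- and age-adjusted dense
#' area on the protein level, and logistic regression of MHT use on the
#' protein level. MHT is coded with never-users as the reference; by default
#' ever-use (before or current) versus never (binomial logistic), or a
#' three-level multinomial model with `mht_coding = "three_level"`.
#'
#' @param x log-scale matrix or [mfi_matrix()] of protein levels.
#' @param shortlisted antibody ids to test.
#' @param annotations sample annotations with `dense_area`, `bmi`, `age`,
#'   `mht_status`.
#' @param mht_coding `"ever"` or `"three_level"`.
#' @return data.frame per protein: dense-area slope and p, MHT log-odds and
#'   p (for `"three_level"`, the smaller of the two contrast p-values and
#'   the corresponding coefficient), and nominal significance flags.
#' @export
trait_association <- function(x, shortlisted, annotations,
                              mht_coding = c("ever", "three_level")) {
  mht_coding <- match.arg(mht_coding)
  v <- if (inherits(x, "mfi_matrix")) log_values(x) else as.matrix(x)
  stopifnot(nrow(annotations) == nrow(v))
  missing_ab <- setdiff(shortlisted, colnames(v))
  if (length(missing_ab)) stop("unknown antibody ids: ",
                               paste(head(missing_ab, 5), collapse = ", "))
  da_use <- complete.cases(annotations[, c("dense_area", "bmi", "age")])
  if (!any(da_use)) stop("dense_area/bmi/age are all missing")
  da_fit <- lm(dense_area ~ bmi + age, data = annotations[da_use, ])
  da_adj <- stats::residuals(da_fit)

  mht <- annotations$mht_status
  mht_use <- !is.na(mht)
  if (!any(mht_use)) stop("mht_status is all missing")

  rows <- lapply(shortlisted, function(ab) {
    prot <- v[, ab]
    fit1 <- lm(da_adj ~ prot[da_use])
    s1 <- summary(fit1)$coefficients
    da_slope <- s1[2, 1]; da_p <- s1[2, 4]

    out <- tryCatch({
      if (mht_coding == "ever") {
        ever <- mht[mht_use] %in% c("before", "current")
        fit2 <- glm(ever ~ prot[mht_use], family = binomial())
        if (!fit2$converged || any(abs(coef(fit2)) > 15)) {
          stop("complete or quasi-complete separation")
        }
        s2 <- summary(fit2)$coefficients
        c(s2[2, 1], s2[2, 4])
      } else {
        f <- factor(mht[mht_use], levels = c("never", "before", "current"))
        fit2 <- nnet::multinom(f ~ prot[mht_use], trace = FALSE)
        co <- summary(fit2)$coefficients[, 2]
        se <- summary(fit2)$standard.errors[, 2]
        pz <- 2 * pnorm(-abs(co / se))
        i <- which.min(pz)
        c(co[i], pz[i])
      }
    }, error = function(e) {
      warning("MHT model skipped for ", ab, ": ", conditionMessage(e))
      c(NA_real_, NA_real_)
    })
    data.frame(antibody_id = ab, dense_area_slope = da_slope, dense_area_p = da_p,
               mht_log_odds = out[1], mht_p = out[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$dense_area_sig <- res$dense_area_p < 0.05
  res$mht_sig <- !is.na(res$mht_p) & res$mht_p < 0.05
  res
}
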