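#' Define a two-group contrast
#'
#' A contrast names a test group and a reference group of samples; per-site
#' methylation differences are reported as test minus reference. The six study
#' contrasts are the aging comparisons among controls (AC-YC, AC-MC, MC-YC;
#' older group is the test group) and the treatment-versus-age-matched-control
#' comparisons (YT-YC, MT-MC, AT-AC; treated group is the test group).
#'
#' @param name contrast label, conventionally `"TEST-REF"`.
#' @param test_samples,reference_samples disjoint, non-empty character vectors
#'   of sample ids.
#' @param alpha_site per-site significance threshold on the raw p-value
#'   (default 0.01; no multiple-testing correction, matching the upstream
#'   pipeline this package reimplements).
#' @param covariates names of sample-sheet columns adjusted for in the
#'   per-site model (default `"kit"`, the library-preparation batch).
#' @return an object of class `mw_contrast_spec`.
#' @export
contrast_spec <- function(name, test_samples, reference_samples,
                          alpha_site = 0.01, covariates = "kit") {
  stopifnot(length(test_samples) >= 1L, length(reference_samples) >= 1L)
  if (length(intersect(test_samples, reference_samples)))
    stop("test and reference groups must be disjoint")
  assert_fraction(alpha_site, "alpha_site", allow_zero = FALSE,
                  allow_one = FALSE)
  structure(list(name = name, test_samples = test_samples,
                 reference_samples = reference_samples,
                 alpha_site = alpha_site, covariates = covariates),
            class = "mw_contrast_spec")
}

#' @rdname contrast_spec
#' @param samples sample sheet `data.table`.
#' @param alpha_site,covariates passed to each [contrast_spec()].
#' @return `study_contrasts()` returns a named list of the six study
#'   contrasts present in the sample sheet.
#' @export
study_contrasts <- function(samples, alpha_site = 0.01, covariates = "kit") {
  samples <- as.data.table(samples)
  grp <- function(g) samples$sample_id[paste0(samples$age,
                                              samples$treatment) == g]
  defs <- list(`AC-YC` = c("AC", "YC"), `AC-MC` = c("AC", "MC"),
               `MC-YC` = c("MC", "YC"), `YT-YC` = c("YT", "YC"),
               `MT-MC` = c("MT", "MC"), `AT-AC` = c("AT", "AC"))
  out <- list()
  for (nm in names(defs)) {
    te <- grp(defs[[nm]][1]); re <- grp(defs[[nm]][2])
    if (length(te) && length(re))
      out[[nm]] <- contrast_spec(nm, te, re, alpha_site = alpha_site,
                                 covariates = covariates)
  }
  out
}

#' Site-retention configuration for a contrast
#'
#' @param min_coverage minimum total reads per site per sample (default 10).
#' @param min_samples_per_group minimum number of samples of each group that
#'   must meet `min_coverage` at a site; `NULL` (default) requires all samples
#'   of both groups.
#' @return an object of class `unite_config`.
#' @export
unite_config <- function(min_coverage = 10L, min_samples_per_group = NULL) {
  min_coverage <- assert_count(min_coverage, "min_coverage")
  if (!is.null(min_samples_per_group))
    min_samples_per_group <- assert_count(min_samples_per_group,
                                          "min_samples_per_group")
  structure(list(min_coverage = min_coverage,
                 min_samples_per_group = min_samples_per_group),
            class = "unite_config")
}

#' Retain sites testable under a contrast
#'
#' Keeps sites whose total count reaches `min_coverage` in at least
#' `min_samples_per_group` samples of BOTH groups, and restricts the container
#' to the contrast's samples.
#'
#' @param counts an [meth_counts()] object.
#' @param contrast an [contrast_spec()].
#' @param config an [unite_config()].
#' @return an [meth_counts()] restaining only testable sites and the
#'   contrast's samples; warns (and returns an empty container) when nothing
#'   survives.
#' @export
unite_sites <- function(counts, contrast, config = unite_config()) {
  stopifnot(inherits(counts, "mw_counts"),
            inherits(contrast, "mw_contrast_spec"),
            inherits(config, "unite_config"))
  missing <- setdiff(c(contrast$test_samples, contrast$reference_samples),
                     counts$samples$sample_id)
  if (length(missing))
    stop("contrast '", contrast$name, "' names samples absent from counts: ",
         paste(missing, collapse = ", "))
  keep_group <- function(ids) {
    m <- counts$total[, ids, drop = FALSE] >= config$min_coverage
    need <- config$min_samples_per_group %||% length(ids)
    rowSums(m) >= min(need, length(ids))
  }
  keep <- keep_group(contrast$test_samples) &
    keep_group(contrast$reference_samples)
  if (!any(keep))
    warning("no site passes the coverage filter for contrast '",
            contrast$name, "'")
  subset_counts(counts, which(keep),
                c(contrast$test_samples, contrast$reference_samples))
}

# Binomial log-likelihood at fitted probabilities (constants dropped).
binom_loglik <- function(meth, total, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(meth * log(p) + (total - meth) * log(1 - p))
}

fit_glm <- function(X, meth, total) {
  suppressWarnings(
    stats::glm.fit(X, meth / total, weights = total,
                   family = stats::binomial())
  )
}

# Rao score test for adding column `xg` to the reduced design `Xr`,
# using the reduced-model fit (separation-robust fallback).
score_test_p <- function(Xr, xg, meth, total, mu0) {
  w <- total * mu0 * (1 - mu0)
  U <- sum(xg * (meth - total * mu0))
  WXr <- Xr * w
  XtWX <- crossprod(Xr, WXr)
  b <- tryCatch(solve(XtWX, crossprod(WXr, xg)), error = function(e) NULL)
  xg_perp <- if (is.null(b)) xg else xg - as.vector(Xr %*% b)
  V <- sum(w * xg_perp^2)
  if (V <= 0) return(1)
  pchisq(U^2 / V, df = 1L, lower.tail = FALSE)
}

#' Per-site covariate-adjusted differential-methylation test
#'
#' Fits a binomial logistic regression of the per-sample (methylated,
#' unmethylated) counts on group plus covariates by maximum likelihood and
#' tests the group term with a 1-df likelihood-ratio chi-square. The reported
#' methylation difference is the unweighted mean of per-sample fractions in
#' the test group minus the reference group (so batch composition cannot
#' masquerade as direction). Degenerate sites (all per-sample fractions
#' identical) return p = 1; perfect separation falls back to the Rao score
#' test; non-convergence returns p = 1 with `flag = "nonconverged"`.
#'
#' @param meth,total per-sample methylated and total counts (equal length;
#'   samples with `total == 0` are excluded).
#' @param is_test logical vector: TRUE for test-group samples.
#' @param covariate optional factor/character covariate (e.g. library kit).
#' @return list with `p_value`, `meth_difference`, `statistic` (LRT
#'   chi-square, NA when the fallback or degenerate path was taken) and
#'   `flag` (`"ok"`, `"degenerate"`, `"separation"`, or `"nonconverged"`).
#' @export
test_site <- function(meth, total, is_test, covariate = NULL) {
  if (!any(is_test) || all(is_test))
    stop("need at least one sample with coverage in each group")
  Xr <- matrix(1, length(meth), 1L)
  if (!is.null(covariate)) {
    f <- factor(covariate)
    if (nlevels(f) > 1L)
      Xr <- cbind(Xr, stats::model.matrix(~f)[, -1L, drop = FALSE])
  }
  test_site_core(meth, total, is_test, Xr)
}

# Fitting core shared by test_site() and run_contrast(); `Xr` is the reduced
# design (intercept + covariates) over all samples, before zero-coverage
# exclusion.
test_site_core <- function(meth, total, is_test, Xr) {
  keep <- total > 0
  if (!all(keep)) {
    meth <- meth[keep]; total <- total[keep]; is_test <- is_test[keep]
    Xr <- Xr[keep, , drop = FALSE]
    if (!any(is_test) || all(is_test))
      stop("need at least one sample with coverage in each group")
  }
  frac <- meth / total
  meth_difference <- mean(frac[is_test]) - mean(frac[!is_test])
  if (all(frac == frac[1L]))
    return(list(p_value = 1, meth_difference = meth_difference,
                statistic = NA_real_, flag = "degenerate"))
  Xf <- cbind(Xr, g = as.numeric(is_test))

  fit_full <- fit_glm(Xf, meth, total)
  fit_red <- fit_glm(Xr, meth, total)
  if (!fit_full$converged || !fit_red$converged) {
    mu0 <- fit_red$fitted.values
    if (fit_red$converged)
      return(list(p_value = score_test_p(Xr, as.numeric(is_test), meth, total,
                                         mu0),
                  meth_difference = meth_difference, statistic = NA_real_,
                  flag = "nonconverged"))
    return(list(p_value = 1, meth_difference = meth_difference,
                statistic = NA_real_, flag = "nonconverged"))
  }
  beta_g <- fit_full$coefficients[["g"]]
  if (!is.finite(beta_g) || abs(beta_g) > 12) {
    # fitted group effect ran to the boundary: perfect separation
    p <- score_test_p(Xr, as.numeric(is_test), meth, total,
                      fit_red$fitted.values)
    return(list(p_value = p, meth_difference = meth_difference,
                statistic = NA_real_, flag = "separation"))
  }
  lrt <- fit_red$deviance - fit_full$deviance
  lrt <- max(lrt, 0)
  list(p_value = pchisq(lrt, df = 1L, lower.tail = FALSE),
       meth_difference = meth_difference, statistic = lrt, flag = "ok")
}

#' Run a full contrast: unite, test every site, classify direction
#'
#' Applies [unite_sites()], runs [test_site()] at every retained site, and
#' classifies each site as `hyper` (p < alpha and difference > 0), `hypo`
#' (p < alpha and difference < 0) or `ns`. A Benjamini-Hochberg adjusted
#' q-value column is emitted for reference but plays no role downstream
#' (significance is on the raw p-value, as in the pipeline this package
#' reimplements).
#'
#' @param counts an [meth_counts()] object.
#' @param contrast an [contrast_spec()].
#' @param config an [unite_config()].
#' @param contexts optional character vector restricting the tested contexts
#'   (e.g. `"CpG"`).
#' @return an object of class `mw_contrast_result`: list with `contrast`,
#'   `results` (`data.table`: `chrom`, `pos`, `strand`, `context`, `p_value`,
#'   `q_value`, `meth_difference`, `direction`, `flag`) and `summary`
#'   (totals plus per-chromosome and per-context hyper/hypo tallies).
#' @export
run_contrast <- function(counts, contrast, config = unite_config(),
                         contexts = NULL) {
  united <- unite_sites(counts, contrast, config)
  if (!is.null(contexts)) {
    rows <- which(united$sites$context %in% contexts)
    united <- subset_counts(united, rows)
  }
  is_test <- united$samples$sample_id %in% contrast$test_samples
  covariate <- NULL
  if (length(contrast$covariates)) {
    miss <- setdiff(contrast$covariates, names(united$samples))
    if (length(miss))
      stop("covariate column(s) missing from sample sheet: ",
           paste(miss, collapse = ", "))
    covariate <- do.call(paste, united$samples[, contrast$covariates,
                                               with = FALSE])
  }
  Xr <- matrix(1, nrow(united$samples), 1L)
  if (!is.null(covariate)) {
    f <- factor(covariate)
    if (nlevels(f) > 1L)
      Xr <- cbind(Xr, stats::model.matrix(~f)[, -1L, drop = FALSE])
  }
  n <- nrow(united$sites)
  p <- diff_ <- numeric(n)
  flag <- character(n)
  meth_m <- united$meth; total_m <- united$total
  for (i in seq_len(n)) {
    r <- test_site_core(meth_m[i, ], total_m[i, ], is_test, Xr)
    p[i] <- r$p_value; diff_[i] <- r$meth_difference; flag[i] <- r$flag
  }
  results <- cbind(united$sites[, .(chrom, pos, strand, context)],
                   data.table(p_value = p, q_value = bh_adjust(p),
                              meth_difference = diff_))
  results[, direction := ifelse(p_value < contrast$alpha_site &
                                  meth_difference > 0, "hyper",
                                ifelse(p_value < contrast$alpha_site &
                                         meth_difference < 0, "hypo", "ns"))]
  results[, flag := flag]
  structure(list(contrast = contrast, results = results,
                 summary = summarize_results(results)),
            class = "mw_contrast_result")
}

summarize_results <- function(results) {
  sig <- results[direction != "ns"]
  by_tab <- function(key) {
    tab <- results[, .(n_hyper = sum(direction == "hyper"),
                       n_hypo = sum(direction == "hypo"),
                       n_tested = .N), by = key]
    setorderv(tab, key)
    tab[]
  }
  list(n_tested = nrow(results),
       n_hyper = sum(results$direction == "hyper"),
       n_hypo = sum(results$direction == "hypo"),
       n_significant = nrow(sig),
       by_chromosome = by_tab("chrom"),
       by_context = by_tab("context"))
}

#' @export
print.mw_contrast_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Contrast %s: %d sites tested; %d significant (%d hyper, %d hypo) at p < %g\n",
              x$contrast$name, s$n_tested, s$n_significant, s$n_hyper,
              s$n_hypo, x$contrast$alpha_site))
  invisible(x)
}

#' Two-sided Fisher exact p-value by enumeration (oracle)
#'
#' Enumerates the full hypergeometric support of the 2x2 table
#' `rbind(c(a, b), c(c, d))` with fixed margins and sums the point
#' probabilities that do not exceed the observed one. This is the package's
#' independent oracle for the covariate-free differential test; it is written
#' directly from the definition and shares no code with [test_site()].
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-sided p-value (1 for the all-zero table).
#' @export
fisher_exact_oracle <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}
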