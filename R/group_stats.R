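# Two-group testing: Wilcoxon rank-sum with an exact small-sample mode,
# the tiered differential-feature procedure, and the Student/Welch t-test
# decision procedure with mean-difference confidence intervals.

# Null distribution of the group-1 rank sum W for sample sizes n1, n2
# (tie-free): number of n1-subsets of ranks 1..n1+n2 with each possible sum,
# by dynamic programming over ranks. Counts are exact in double precision for
# the sizes where the exact mode applies.
.ranksum_null <- function(n1, n2) {
  n <- n1 + n2
  smax <- sum((n - n1 + 1L):n)
  smin <- sum(seq_len(n1))
  # dp[k+1, s+1] = #subsets of size k with sum s
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1L) {
      smaxk <- sum((i - k + 1L):i)
      src <- seq_len(smaxk - i + 1L)
      dp[k + 1L, src + i] <- dp[k + 1L, src + i] + dp[k, src]
    }
  }
  list(w = smin:smax, count = dp[n1 + 1L, (smin:smax) + 1L],
       total = choose(n, n1))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test reporting W, the rank sum of the first group
#' (average ranks on ties). In `"exact"` mode the P value comes from full
#' enumeration of the null rank-sum distribution (only valid without ties);
#' in `"normal"` mode from the normal approximation with tie correction and a
#' continuity correction. `"auto"` uses the exact mode when
#' `min(n1, n2) <= 12` and the data are tie-free, matching mainstream
#' implementations so P values are comparable.
#'
#' @param x,y Numeric vectors, one per group (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `W`, `p.value`, and the `mode` actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) ftx_usage_error("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) ftx_usage_error("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  z <- c(x, y)
  r <- rank(z)
  ties <- anyDuplicated(z) > 0L
  W <- sum(r[seq_len(n1)])
  if (mode == "auto") mode <- if (min(n1, n2) <= 12L && !ties) "exact" else "normal"
  if (mode == "exact") {
    if (ties) {
      ftx_usage_error("exact mode is undefined with ties; use mode = 'normal'")
    }
    null <- .ranksum_null(n1, n2)
    p_le <- sum(null$count[null$w <= W]) / null$total
    p_ge <- sum(null$count[null$w >= W]) / null$total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n1 * (n + 1) / 2
    tiecnt <- table(z)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tiecnt^3 - tiecnt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- W - mu
      zstat <- (d - sign(d) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    }
  }
  list(W = W, p.value = p, mode = mode)
}

.tier <- function(p, sig_alpha, trend_alpha) {
  ifelse(p < sig_alpha, "significant",
         ifelse(p < trend_alpha, "trend", "ns"))
}

#' Differential abundance testing of a feature profile
#'
#' Runs a two-sided Wilcoxon rank-sum test per feature between the two design
#' groups, by default on within-sample relative abundances. Features constant
#' across all samples are skipped (listed in the `"skipped"` attribute).
#' Tiers follow the configured alphas (`significant` for `P < sig_alpha`,
#' `trend` for `sig_alpha <= P < trend_alpha`, else `ns`); direction is the
#' group with the larger median (larger mean on median ties).
#' Benjamini-Hochberg q-values are added as a convenience column; the tiers
#' themselves are based on raw P values.
#'
#' @param profile Samples x features abundance matrix.
#' @param design `sample_design` covering the profile's samples.
#' @param config An [analysis_config()].
#' @param use_relative Test within-sample relative abundances (default) or
#'   raw values.
#' @param mode Wilcoxon mode passed to [wilcoxon_rank_sum()].
#' @return `data.frame` with one row per tested feature, sorted by P then
#'   feature id, columns `feature_id`, per-group means and medians, `W`, `P`,
#'   `q_BH`, `tier`, `direction`.
#' @export
differential_features <- function(profile, design, config = analysis_config(),
                                  use_relative = TRUE, mode = "auto") {
  design <- validate_design(as.data.frame(design))
  miss <- setdiff(design$sample_id, rownames(profile))
  if (length(miss)) {
    ftx_design_error(sprintf("design sample '%s' absent from profile", miss[1]))
  }
  m <- profile[design$sample_id, , drop = FALSE]
  if (use_relative) {
    tot <- rowSums(m)
    if (any(tot <= 0)) ftx_format_error("sample with zero total abundance")
    m <- m / tot
  }
  pos <- positive_group(design)
  neg <- setdiff(unique(design$group), pos)
  i1 <- design$group == pos
  i2 <- design$group == neg
  feats <- colnames(m)
  keep <- apply(m, 2L, function(v) max(v) > min(v))
  skipped <- feats[!keep]
  if (length(skipped)) {
    ftx_log(sprintf("skipping %d constant feature(s): %s%s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", "),
                    if (length(skipped) > 5) ", ..." else ""))
  }
  feats <- feats[keep]
  rows <- lapply(feats, function(f) {
    v1 <- m[i1, f]; v2 <- m[i2, f]
    wt <- wilcoxon_rank_sum(v1, v2, mode = mode)
    med1 <- stats::median(v1); med2 <- stats::median(v2)
    mean1 <- mean(v1); mean2 <- mean(v2)
    dir <- if (med1 > med2) pos else if (med2 > med1) neg
    else if (mean1 >= mean2) pos else neg
    data.frame(feature_id = f, mean_pos = mean1, mean_neg = mean2,
               median_pos = med1, median_neg = med2,
               W = wt$W, P = wt$p.value, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), mean_pos = numeric(),
               mean_neg = numeric(), median_pos = numeric(),
               median_neg = numeric(), W = numeric(), P = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_pos"] <- paste0("mean_", pos)
  names(out)[names(out) == "mean_neg"] <- paste0("mean_", neg)
  names(out)[names(out) == "median_pos"] <- paste0("median_", pos)
  names(out)[names(out) == "median_neg"] <- paste0("median_", neg)
  out$q_BH <- if (nrow(out)) stats::p.adjust(out$P, method = "BH") else numeric()
  out$tier <- .tier(out$P, config$sig_alpha, config$trend_alpha)
  out <- out[order(out$P, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "positive_group") <- pos
  class(out) <- c("differential_table", "data.frame")
  out
}

# Brown-Forsythe variant of Levene's test (median-centered), two groups.
.levene_bf <- function(x, y) {
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  if (stats::var(z) == 0) return(list(statistic = 0, p.value = 1))
  ft <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

#' Phenotype comparison with pre-tested t-test choice
#'
#' Per-group Shapiro-Wilk normality tests (skipped with a warning when a
#' group has fewer than 3 values), a median-centered (Brown-Forsythe) Levene
#' test for homogeneity of variance, and then a two-sided Student t-test, or
#' Welch's t-test when the variance test rejects at `var_alpha`
#' (Welch-Satterthwaite degrees of freedom). Normality failures are warned
#' about but do not change the test branch. The difference and its 95%
#' confidence interval are oriented `x - y`.
#'
#' @param x,y Numeric vectors (first group minus second in all differences).
#' @param trait Optional trait name carried into the output.
#' @param var_alpha Rejection level for the variance pre-test.
#' @return One-row `data.frame` with group summaries, pre-test P values, the
#'   chosen test, t, df, P, and the 95% CI of the mean difference.
#' @export
phenotype_compare <- function(x, y, trait = NA_character_, var_alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) {
    ftx_usage_error("each group needs >= 2 values")
  }
  sw_x <- sw_y <- NA_real_
  if (min(length(x), length(y)) >= 3L && stats::var(x) > 0 && stats::var(y) > 0) {
    sw_x <- stats::shapiro.test(x)$p.value
    sw_y <- stats::shapiro.test(y)$p.value
    if (min(sw_x, sw_y) < 0.05) {
      warning("normality pre-test rejected (P < 0.05); t-test reported anyway",
              call. = FALSE)
    }
  } else if (min(length(x), length(y)) < 3L) {
    warning("group too small for the normality pre-test; step skipped",
            call. = FALSE)
  }
  lev <- .levene_bf(x, y)
  welch <- lev$p.value < var_alpha
  tt <- stats::t.test(x, y, var.equal = !welch, conf.level = 0.95)
  data.frame(trait = trait,
             n_x = length(x), n_y = length(y),
             mean_x = mean(x), sd_x = stats::sd(x),
             mean_y = mean(y), sd_y = stats::sd(y),
             shapiro_p_x = sw_x, shapiro_p_y = sw_y,
             levene_p = lev$p.value,
             test = if (welch) "welch" else "student",
             t = unname(tt$statistic), df = unname(tt$parameter),
             P = tt$p.value,
             diff = mean(x) - mean(y),
             ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
             stringsAsFactors = FALSE)
}

#' Welch confidence interval for a difference of means
#'
#' Difference of means oriented first group minus second, with a
#' Welch-Satterthwaite t interval at the requested level.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param level Confidence level in (0, 1).
#' @return List with `estimate`, `lower`, `upper`, `df`, `level`.
#' @export
mean_difference_ci <- function(x, y, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || !(level > 0 && level < 1)) {
    ftx_usage_error("level must lie in (0, 1)")
  }
  if (length(x) < 2L || length(y) < 2L) {
    ftx_usage_error("each group needs >= 2 values")
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  est <- mean(x) - mean(y)
  se <- sqrt(vx + vy)
  if (se == 0) {
    return(list(estimate = est, lower = est, upper = est, df = NA_real_,
                level = level))
  }
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  h <- stats::qt(1 - (1 - level) / 2, df) * se
  list(estimate = est, lower = est - h, upper = est + h, df = df,
       level = level)
}

#' Compare all phenotype traits between the design groups
#'
#' Convenience wrapper running [phenotype_compare()] for every numeric column
#' of a phenotype table, oriented positive group minus negative group
#' (LFCR - HFCR when those labels are used).
#'
#' @param phenotypes `data.frame` with a `sample_id` column and numeric traits.
#' @param design `sample_design`.
#' @return `data.frame`, one row per trait.
#' @export
phenotype_compare_table <- function(phenotypes, design) {
  design <- validate_design(as.data.frame(design))
  idx <- match(design$sample_id, phenotypes$sample_id)
  if (anyNA(idx)) {
    ftx_design_error(sprintf("sample '%s' missing from phenotype table",
                             design$sample_id[which(is.na(idx))[1]]))
  }
  ph <- phenotypes[idx, , drop = FALSE]
  pos <- positive_group(design)
  traits <- names(ph)[vapply(ph, is.numeric, TRUE) & names(ph) != "sample_id"]
  rows <- lapply(traits, function(tr) {
    suppressWarnings(phenotype_compare(ph[[tr]][design$group == pos],
                                       ph[[tr]][design$group != pos],
                                       trait = tr))
  })
  out <- do.call(rbind, rows)
  attr(out, "positive_group") <- pos
  out
}
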