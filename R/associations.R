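#' Pooled and per-stratum correlation
#'
#' Correlates two sample-level variables overall and within each level of
#' a stratifying label (e.g. medicated vs non-medicated), reporting r, p
#' and n for the pooled cohort and for every stratum with at least
#' `min_n` samples; smaller strata are reported as skipped.
#'
#' @param records `data.frame` with one row per sample.
#' @param stratum_label Column name holding the stratum labels.
#' @param x_field,y_field Column names of the two variables.
#' @param min_n Minimum stratum size (default 3).
#' @param method `"spearman"` (default; see [spearman_correlation()]).
#' @return `data.frame` with `stratum` (`"pooled"` first), `r`, `p`, `n`,
#'   `skipped`.
#' @export
stratified_correlation <- function(records, stratum_label, x_field,
                                   y_field, min_n = 3L,
                                   method = "spearman") {
  stopifnot(all(c(stratum_label, x_field, y_field) %in% names(records)))
  run <- function(d, label) {
    if (nrow(d) < min_n) {
      return(data.frame(stratum = label, r = NA_real_, p = NA_real_,
                        n = nrow(d), skipped = TRUE))
    }
    ct <- spearman_correlation(d[[x_field]], d[[y_field]])
    data.frame(stratum = label, r = ct$r, p = ct$p, n = ct$n,
               skipped = FALSE)
  }
  out <- rbind(
    run(records, "pooled"),
    do.call(rbind, lapply(split(records, records[[stratum_label]]),
                          function(d) run(d, as.character(
                            d[[stratum_label]][1])))))
  rownames(out) <- NULL
  out
}

#' Within-pair contrasts for a monozygotic twin cohort
#'
#' For BMI-discordant monozygotic twin pairs, compares each trait within
#' pairs (heavier minus leaner co-twin by BMI) with the paired Wilcoxon
#' signed-rank test, and correlates the within-pair absolute copy-number
#' difference with pair age and with the BMI discordance. Because
#' co-twins share their germline, a null within-pair copy-number test
#' argues that copy number is inherited rather than remodelled by the
#' phenotype.
#'
#' @param records `data.frame` with one row per individual: columns
#'   `sample_id`, `twin_pair_id`, `bmi`, plus any of `cn`, `methylation`,
#'   `age`.
#' @param traits Traits to test within pairs (default those present among
#'   `bmi`, `cn`, `methylation`).
#' @return List with `paired_tests` (`data.frame`: trait, W, p, n; `p`
#'   is `NA` with note `"no difference detectable"` when all within-pair
#'   differences are zero), `delta_correlations` (`|dCN|` vs age and vs
#'   `|dBMI|`), and `pairs` (per-pair deltas).
#' @export
twin_pair_analysis <- function(records,
                               traits = intersect(
                                 c("bmi", "cn", "methylation"),
                                 names(records))) {
  stopifnot(all(c("sample_id", "twin_pair_id", "bmi") %in% names(records)))
  sizes <- table(records$twin_pair_id)
  if (any(sizes != 2L)) {
    stop("incomplete twin pair(s): ",
         paste(names(sizes)[sizes != 2L], collapse = ", "))
  }
  by_pair <- split(records, records$twin_pair_id)
  pairs <- do.call(rbind, lapply(by_pair, function(p) {
    p <- p[order(-p$bmi), , drop = FALSE]  # heavier co-twin first
    row <- data.frame(twin_pair_id = p$twin_pair_id[1])
    for (tr in traits) {
      row[[paste0(tr, "_heavier")]] <- p[[tr]][1]
      row[[paste0(tr, "_leaner")]] <- p[[tr]][2]
      row[[paste0("d_", tr)]] <- p[[tr]][1] - p[[tr]][2]
    }
    if ("age" %in% names(p)) row$age <- mean(p$age)
    row
  }))
  rownames(pairs) <- NULL

  paired_tests <- do.call(rbind, lapply(traits, function(tr) {
    hx <- pairs[[paste0(tr, "_heavier")]]
    lx <- pairs[[paste0(tr, "_leaner")]]
    res <- tryCatch(wilcoxon_signed_rank_paired(hx, lx),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(trait = tr, W = NA_real_, p = NA_real_,
                 n = nrow(pairs), note = "no difference detectable")
    } else {
      data.frame(trait = tr, W = res$W, p = res$p, n = res$n, note = "")
    }
  }))

  delta_correlations <- NULL
  if ("cn" %in% traits) {
    abs_dcn <- abs(pairs$d_cn)
    rows <- list()
    if ("age" %in% names(pairs) && length(unique(abs_dcn)) > 1L) {
      ct <- spearman_correlation(abs_dcn, pairs$age)
      rows <- c(rows, list(data.frame(contrast = "abs_dCN_vs_age",
                                      r = ct$r, p = ct$p, n = ct$n)))
    }
    if (length(unique(abs_dcn)) > 1L) {
      ct <- spearman_correlation(abs_dcn, abs(pairs$d_bmi))
      rows <- c(rows, list(data.frame(contrast = "abs_dCN_vs_abs_dBMI",
                                      r = ct$r, p = ct$p, n = ct$n)))
    }
    if (length(rows)) delta_correlations <- do.call(rbind, rows)
  }

  list(paired_tests = paired_tests,
       delta_correlations = delta_correlations,
       pairs = pairs)
}

#' Fit an exponential-plateau growth curve
#'
#' Fits the saturating growth model
#' \deqn{W(t) = Y_M - (Y_M - Y_0)\,e^{-k t}}
#' by nonlinear least squares over a deterministic multi-start grid
#' (starting values: `Y0` at the first observation, `YM` at 1.1/1.5/2
#' times the maximum observation, `k` in 0.05/0.2/0.5/1 per week), with
#' positivity constraints on `k` and on the growth span `YM - Y0`. The
#' best-SSE fit wins; ties go to the smallest `k`.
#'
#' @param week Numeric vector of ages (weeks), strictly increasing.
#' @param weight Positive weights (grams), same length, >= 4 points.
#' @return List of class `growth_fit`: `ym`, `y0`, `k`, `r_squared`,
#'   `fitted`, `residuals`, `sse`.
#' @export
fit_exponential_plateau <- function(week, weight) {
  stopifnot(length(week) == length(weight))
  if (length(week) < 4L) stop("need at least 4 time points")
  if (any(weight <= 0)) stop("weights must be positive")
  if (length(unique(weight)) == 1L) {
    stop("constant series: no growth to fit")
  }
  dat <- data.frame(t = week, w = weight)
  ym_grid <- c(1.1, 1.5, 2) * max(weight)
  k_grid <- c(0.05, 0.2, 0.5, 1)
  y0_start <- weight[which.min(week)]
  best <- NULL
  # fit on (ym, span = ym - y0, k) so the positivity constraints are the
  # stated ones: k > 0 and growth span ym - y0 > 0; y0 itself (the value
  # extrapolated to t = 0) is unconstrained
  for (ym0 in ym_grid) for (k0 in k_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        w ~ ym - span * exp(-k * t), data = dat,
        start = list(ym = ym0, span = ym0 - y0_start, k = k0),
        lower = c(ym = -Inf, span = 1e-8, k = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    k_hat <- stats::coef(fit)[["k"]]
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && k_hat < best$k)) {
      best <- list(fit = fit, sse = sse, k = k_hat)
    }
  }
  if (is.null(best)) stop("plateau fit did not converge from any start")
  cf <- stats::coef(best$fit)
  if (cf[["span"]] <= 1e-6) {
    stop("fitted growth span is degenerate: not growth data ",
         "(best residual SSE ", signif(best$sse, 6), ")")
  }
  fitted <- stats::fitted(best$fit)
  ss_tot <- sum((weight - mean(weight))^2)
  structure(list(ym = unname(cf[["ym"]]),
                 y0 = unname(cf[["ym"]] - cf[["span"]]),
                 k = unname(cf[["k"]]),
                 r_squared = 1 - best$sse / ss_tot,
                 fitted = as.numeric(fitted),
                 residuals = as.numeric(weight - fitted),
                 sse = best$sse),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "exponential plateau fit: YM=%.4g, Y0=%.4g, k=%.4g /week, R^2=%.4f\n",
    x$ym, x$y0, x$k, x$r_squared))
  invisible(x)
}

#' Per-week and weight-gain correlations with copy number
#'
#' Cross-sectional view of when a copy-number association with body mass
#' emerges: for every observed week, the weights of all animals are
#' correlated (Spearman) with their rDNA copy number; additionally the
#' overall weight gain (last-week minus first-week weight per animal) is
#' correlated with copy number. Raw p-values are primary; a
#' Holm-adjusted column is provided for the per-week table.
#'
#' @param weights Long-format `data.frame` with `sample_id`, `week`,
#'   `weight`.
#' @param cn Copy-number table (`sample_id`, `value`).
#' @return List with `per_week` (`week`, `r`, `p`, `p_holm`, `n`) and
#'   `gain` (`r`, `p`, `n`, `first_week`, `last_week`).
#' @export
cross_sectional_growth_correlation <- function(weights, cn) {
  stopifnot(all(c("sample_id", "week", "weight") %in% names(weights)))
  shared <- intersect(unique(weights$sample_id), cn$sample_id)
  if (length(shared) < 3L) stop("fewer than 3 overlapping samples")
  weights <- weights[weights$sample_id %in% shared, , drop = FALSE]
  cn_val <- cn$value[match(shared, cn$sample_id)]
  names(cn_val) <- shared

  weeks <- sort(unique(weights$week))
  per_week <- do.call(rbind, lapply(weeks, function(wk) {
    d <- weights[weights$week == wk, , drop = FALSE]
    ct <- spearman_correlation(d$weight, cn_val[d$sample_id])
    data.frame(week = wk, r = ct$r, p = ct$p, n = ct$n)
  }))
  per_week$p_holm <- stats::p.adjust(per_week$p, method = "holm")

  first_wk <- min(weeks); last_wk <- max(weeks)
  gain <- vapply(shared, function(s) {
    d <- weights[weights$sample_id == s, , drop = FALSE]
    if (!(first_wk %in% d$week) || !(last_wk %in% d$week)) {
      stop("sample ", s, " lacks an endpoint observation")
    }
    d$weight[d$week == last_wk] - d$weight[d$week == first_wk]
  }, numeric(1))
  gt <- spearman_correlation(gain, cn_val[shared])
  list(per_week = per_week,
       gain = list(r = gt$r, p = gt$p, n = gt$n,
                   first_week = first_wk, last_week = last_wk))
}
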