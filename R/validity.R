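# Concurrent-validity statistics over paired per-trial samples: descriptives
# with t-based confidence intervals, paired mean differences, and
# normality-gated Pearson/Spearman correlations with strength labels.

#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper: sample size must be in \[3, 5000\] and the vector
#' non-constant.
#'
#' @param x Numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  if (stats::sd(x) == 0) stop("Shapiro-Wilk undefined for a constant vector")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Normality-gated correlation
#'
#' Pearson's r when both vectors pass the Shapiro-Wilk test at `alpha`,
#' otherwise Spearman's rho (computed on average ranks, asymptotic two-sided
#' p-value).
#'
#' @param a,b Paired numeric vectors.
#' @param alpha Normality gate level (default 0.05).
#' @return List with `coefficient`, `kind` ("pearson" or "spearman") and `p`.
#' @export
correlation <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined when either vector has zero variance")
  normal <- shapiro_wilk(a)$p >= alpha && shapiro_wilk(b)$p >= alpha
  kind <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(a, b, method = kind, exact = FALSE))
  list(coefficient = unname(ct$estimate), kind = kind, p = ct$p.value)
}

#' Correlation strength label
#'
#' Piecewise-constant on the absolute coefficient with breakpoints
#' 0.3, 0.6, 0.8 and 1: poor, fair, moderate, very strong, perfect (the sign
#' is reported separately, negative coefficients label "inversely").
#'
#' @param coefficient Correlation coefficient in \[-1, 1\].
#' @return Character label.
#' @export
classify_strength <- function(coefficient) {
  if (!is.finite(coefficient) || abs(coefficient) > 1 + 1e-12)
    stop("coefficient must lie in [-1, 1]")
  r <- min(abs(coefficient), 1)
  if (r == 1) "perfect"
  else if (r >= 0.8) "very strong"
  else if (r >= 0.6) "moderate"
  else if (r >= 0.3) "fair"
  else "poor"
}

#' Mean, SD and t-based confidence interval of a sample
#'
#' @param x Numeric vector (n >= 2).
#' @param confidence Confidence level (default 0.95).
#' @return List with `mean`, `sd` (n-1 denominator) and `ci` (length 2).
#' @export
mean_sd_ci <- function(x, confidence = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 observations")
  m <- mean(x); s <- stats::sd(x)
  list(mean = m, sd = s, ci = ci_from_summary(m, s, length(x), confidence))
}

#' t-based confidence interval from summary statistics
#'
#' `mean +/- t(1 - (1-confidence)/2, n-1) * sd / sqrt(n)`; reproduces
#' published interval bounds from printed means and SDs.
#'
#' @param mean,sd,n Sample mean, SD and size.
#' @param confidence Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
ci_from_summary <- function(mean, sd, n, confidence = 0.95) {
  if (n < 2L) stop("need at least 2 observations")
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1L) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Paired mean difference with t-based confidence interval
#'
#' Direction is fixed as `b - a` (new system minus reference system).
#'
#' @param a Reference-system values.
#' @param b New-system values, paired with `a`.
#' @param confidence Confidence level (default 0.95).
#' @return List with `mean`, `sd` (of the paired differences) and `ci`.
#' @export
mean_diff_ci <- function(a, b, confidence = 0.95) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- b - a
  mean_sd_ci(d, confidence)
}

#' Build the concurrent-validity table
#'
#' For every variable and trial, paired across subjects: per-system mean, SD
#' and 95% CI; mean difference (new minus reference) with 95% CI; the
#' normality-gated correlation with strength label and significance at
#' `alpha`. Mirrors the layout of a per-trial agreement table (five variables
#' by three trials under the default cohort).
#'
#' @param peaks Long peaks data frame with columns `subject`, `trial`,
#'   `modality` and the five variables (as produced by [run_study()] or read
#'   back via [read_peaks_csv()]).
#' @param reference,new Modality tags of the reference and new system.
#' @param alpha Significance level (default 0.05; no multiple-testing
#'   correction is applied).
#' @param confidence CI level (default 0.95).
#' @return A `validity_table`: data frame with one row per variable x trial,
#'   printable as an aligned plain-text table.
#' @export
build_validity_table <- function(peaks, reference = "optical", new = "sensor",
                                 alpha = 0.05, confidence = 0.95) {
  vars <- names(.extract_vars)
  need <- c("subject", "trial", "modality", vars)
  if (!all(need %in% names(peaks)))
    stop("peaks table must have columns: ", paste(need, collapse = ", "))
  trials <- sort(unique(peaks$trial))
  rows <- list()
  for (tr in trials) {
    pa <- peaks[peaks$trial == tr & peaks$modality == reference, ]
    pb <- peaks[peaks$trial == tr & peaks$modality == new, ]
    missing_a <- setdiff(pb$subject, pa$subject)
    missing_b <- setdiff(pa$subject, pb$subject)
    if (length(missing_a) || length(missing_b))
      stop(sprintf("trial %s: unpaired subjects (missing %s: %s; missing %s: %s)",
                   tr, reference, paste(missing_a, collapse = ","),
                   new, paste(missing_b, collapse = ",")))
    pa <- pa[order(pa$subject), ]; pb <- pb[order(pb$subject), ]
    if (anyDuplicated(pa$subject) || anyDuplicated(pb$subject))
      stop(sprintf("trial %s: duplicated subject rows", tr))
    for (v in vars) {
      a <- pa[[v]]; b <- pb[[v]]
      sa <- mean_sd_ci(a, confidence); sb <- mean_sd_ci(b, confidence)
      dd <- mean_diff_ci(a, b, confidence)
      co <- correlation(a, b, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, variable = v, n = length(a),
        ref_mean = sa$mean, ref_sd = sa$sd, ref_ci_low = sa$ci[1L], ref_ci_high = sa$ci[2L],
        new_mean = sb$mean, new_sd = sb$sd, new_ci_low = sb$ci[1L], new_ci_high = sb$ci[2L],
        mean_diff = dd$mean, diff_ci_low = dd$ci[1L], diff_ci_high = dd$ci[2L],
        coefficient = co$coefficient, kind = co$kind,
        strength = classify_strength(co$coefficient),
        p_value = co$p, significant = co$p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("validity_table", "data.frame"),
            reference = reference, new = new, alpha = alpha,
            confidence = confidence, peaks = peaks)
}

#' @export
print.validity_table <- function(x, digits = 1, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  ref <- attr(x, "reference"); new <- attr(x, "new")
  pretty <- c(knee_flexion = "Knee flexion", hip_flexion = "Hip flexion",
              hip_sway = "Hip ab-adduction", spine_flexion = "Spine flexion",
              spine_sway = "Spine lat. flexion")
  for (tr in unique(x$trial)) {
    cat(sprintf("Trial %s (n = %d)\n", tr, x$n[x$trial == tr][1L]))
    block <- x[x$trial == tr, ]
    tab <- rbind(
      sprintf("%s (%s) (%s-%s)", fmt(block$ref_mean), fmt(block$ref_sd),
              fmt(block$ref_ci_low), fmt(block$ref_ci_high)),
      sprintf("%s (%s) (%s-%s)", fmt(block$new_mean), fmt(block$new_sd),
              fmt(block$new_ci_low), fmt(block$new_ci_high)),
      sprintf("%s (%s-%s)", fmt(block$mean_diff),
              fmt(block$diff_ci_low), fmt(block$diff_ci_high)),
      sprintf("%s = %.3f%s [%s]",
              ifelse(block$kind == "pearson", "r", "rho"), block$coefficient,
              ifelse(block$significant, "*", ""), block$strength))
    dimnames(tab) <- list(c(sprintf("  %s (deg)", ref), sprintf("  %s (deg)", new),
                            "  Mean diff (95%CI)", "  Correlation"),
                          pretty[block$variable])
    print(tab, quote = FALSE, right = TRUE)
    cat("\n")
  }
  cat(sprintf("Mean difference direction: %s - %s. * p < %g (no multiple-testing correction).\n",
              new, ref, attr(x, "alpha")))
  invisible(x)
}

#' @export
summary.validity_table <- function(object, ...) {
  sag <- object$variable %in% c("knee_flexion", "hip_flexion", "spine_flexion")
  out <- list(
    n = object$n[1L],
    trials = length(unique(object$trial)),
    sagittal_range = range(object$coefficient[sag]),
    frontal_range = range(object$coefficient[!sag]),
    max_abs_mean_diff = max(abs(object$mean_diff)))
  class(out) <- "summary.validity_table"
  out
}

#' @export
print.summary.validity_table <- function(x, ...) {
  cat("Concurrent validity across", x$trials, "trial(s), n =", x$n, "subjects\n")
  cat(sprintf("  sagittal-plane correlations: %.3f-%.3f\n",
              x$sagittal_range[1L], x$sagittal_range[2L]))
  cat(sprintf("  frontal-plane correlations:  %.3f-%.3f\n",
              x$frontal_range[1L], x$frontal_range[2L]))
  cat(sprintf("  largest |mean difference|:   %.1f deg\n", x$max_abs_mean_diff))
  invisible(x)
}

#' Scatter plots of new-system against reference-system values
#'
#' One panel per variable, trials pooled, with the identity line.
#'
#' @param x A `validity_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.validity_table <- function(x, ...) {
  peaks <- attr(x, "peaks")
  ref <- attr(x, "reference"); new <- attr(x, "new")
  vars <- unique(x$variable)
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    a <- peaks[peaks$modality == ref, ]
    b <- peaks[peaks$modality == new, ]
    key <- paste(a$subject, a$trial)
    bv <- b[[v]][match(key, paste(b$subject, b$trial))]
    graphics::plot(a[[v]], bv, xlab = paste(ref, "(deg)"), ylab = paste(new, "(deg)"),
                   main = v, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Write a validity table to CSV
#' @param x A `validity_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validity_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
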