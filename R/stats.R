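# --- method-agreement statistics ------------------------------------------
#
# The statistics used to evaluate an imaging-based wear method against a
# reference: Bland-Altman differences with 1.96-SD limits of agreement, a
# t-based interval estimate of the bias, ISO 3534-style repeatability from
# duplicate measurements, 95%-level accuracy (bias plus random error), a
# per-cup summary table, and creep estimated from soak controls. Sample SDs
# use the n-1 denominator throughout.

#' Bland-Altman agreement between two methods
#'
#' Computes the per-unit differences `a - b`, their mean (the bias), sample
#' SD, the 95% limits of agreement `mean ± 1.96 SD`, and a t-based 95%
#' confidence interval for the bias (see [bias_interval]).
#'
#' @param method_a,method_b paired measurement vectors (same units, same
#'   length, at least 2 pairs). `method_a` may also be a data frame with
#'   columns `method_a` and `method_b`.
#' @param confidence confidence level for the bias interval (default 0.95)
#' @return object of class `agreement_summary` with `n`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `bias_ci_low`, `bias_ci_high`
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))
#' @export
bland_altman <- function(method_a, method_b = NULL, confidence = 0.95) {
  if (is.data.frame(method_a) && is.null(method_b)) {
    method_b <- method_a$method_b
    method_a <- method_a$method_a
  }
  a <- as.numeric(method_a)
  b <- as.numeric(method_b)
  if (length(a) != length(b)) abort_parse("paired vectors differ in length")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort_parse("non-finite measurement value")
  }
  d <- a - b
  if (length(d) < 2L) abort_parse("need at least 2 paired measurements")
  m <- mean(d)
  s <- sd(d)
  ci <- bias_interval(d, confidence = confidence)
  structure(list(n = length(d), mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 bias_ci_low = ci[1], bias_ci_high = ci[2],
                 confidence = confidence, differences = d,
                 means = (a + b) / 2),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d\n", x$n))
  cat(sprintf("  mean difference (bias): %.4f (SD %.4f)\n",
              x$mean_difference, x$sd_difference))
  cat(sprintf("  %.0f%% bias CI: [%.4f, %.4f]\n", 100 * x$confidence,
              x$bias_ci_low, x$bias_ci_high))
  cat(sprintf("  limits of agreement: [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  if (!is.null(x$repeatability)) {
    cat(sprintf("  repeatability: %.4f\n", x$repeatability))
  }
  if (!is.null(x$accuracy)) cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' t-based interval estimate of the bias
#'
#' `mean(d) ± t[(1+conf)/2, n-1] * SD(d) / sqrt(n)`: the Student-t
#' confidence interval for the mean difference.
#'
#' @param differences numeric vector of differences (n >= 2)
#' @param confidence confidence level in (0, 1), default 0.95
#' @return length-2 vector `c(low, high)`
#' @examples
#' bias_interval(c(-1, 0, 1)) # 0 -/+ 4.3027/sqrt(3)
#' @export
bias_interval <- function(differences, confidence = 0.95) {
  d <- as.numeric(differences)
  if (length(d) < 2L) abort_parse("need at least 2 differences")
  if (confidence <= 0 || confidence >= 1) {
    abort_parse("confidence must be in (0, 1)")
  }
  half <- qt((1 + confidence) / 2, df = length(d) - 1) * sd(d) / sqrt(length(d))
  c(mean(d) - half, mean(d) + half)
}

#' ISO-style repeatability from duplicate measurements
#'
#' For units each measured twice under repeatability conditions, the
#' within-unit SD is `s_w = sqrt(sum(d_i^2) / (2 n))` over the duplicate
#' differences `d_i`, and the repeatability at the 95% level is
#' `1.96 * sqrt(2) * s_w` (~ `2.77 s_w`): the value below which the absolute
#' difference of two repeated measurements falls with 95% probability. The
#' alternative convention `1.96 * SD(d)` (sample SD of the duplicate
#' differences) is available via `method = "sd_of_differences"`.
#'
#' @param replicate_pairs two-column matrix or data frame: one row per unit,
#'   the two replicate measurements in the columns
#' @param method `"duplicate"` (default) or `"sd_of_differences"`
#' @return repeatability in the units of the input
#' @examples
#' repeatability_iso(cbind(c(1, 1), c(0.9, 1.1))) # 0.196
#' @export
repeatability_iso <- function(replicate_pairs,
                              method = c("duplicate", "sd_of_differences")) {
  method <- match.arg(method)
  m <- as.matrix(replicate_pairs)
  if (ncol(m) != 2L) {
    abort_parse("replicate_pairs needs exactly 2 replicates per unit")
  }
  if (nrow(m) < 2L) abort_parse("need at least 2 units")
  if (!all(is.finite(m))) {
    abort_parse("every unit needs both replicate measurements (finite)")
  }
  d <- m[, 1] - m[, 2]
  if (method == "duplicate") {
    s_w <- sqrt(sum(d^2) / (2 * length(d)))
    1.96 * sqrt(2) * s_w
  } else {
    1.96 * sd(d)
  }
}

#' 95%-level accuracy against a reference
#'
#' Accuracy combines the systematic error (bias) and the random error of a
#' method against an accepted reference: `|mean(d)| + 1.96 * SD(d)` over the
#' method-minus-reference differences.
#'
#' @param differences method-minus-reference differences (n >= 2)
#' @return accuracy in the units of the input (always `>= |mean|`)
#' @examples
#' accuracy_95(c(0.1, -0.1, 0.2, -0.2)) # 0.3579
#' @export
accuracy_95 <- function(differences) {
  d <- as.numeric(differences)
  if (length(d) < 2L) abort_parse("need at least 2 differences")
  abs(mean(d)) + 1.96 * sd(d)
}

#' Per-cup wear summary table
#'
#' Builds the standard method-comparison table: one row per cup with the
#' two methods' means (and replicate SDs when provided), a difference
#' column, and an `All cups` row of column means.
#'
#' @param per_cup data frame with columns `cup`, `ct_mean`, `cmm_mean`, and
#'   optionally `ct_sd`, `cmm_sd`
#' @return data frame with the added `difference` column and a final
#'   `All cups` summary row
#' @export
summarize_wear_table <- function(per_cup) {
  req <- c("cup", "ct_mean", "cmm_mean")
  if (!all(req %in% names(per_cup))) {
    abort_parse("per_cup needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(per_cup) < 1L) abort_parse("need at least one cup")
  tab <- data.frame(cup = as.character(per_cup$cup),
                    ct_mean = per_cup$ct_mean,
                    ct_sd = if ("ct_sd" %in% names(per_cup)) per_cup$ct_sd else NA_real_,
                    cmm_mean = per_cup$cmm_mean,
                    cmm_sd = if ("cmm_sd" %in% names(per_cup)) per_cup$cmm_sd else NA_real_,
                    stringsAsFactors = FALSE)
  tab$difference <- tab$ct_mean - tab$cmm_mean
  all_row <- data.frame(cup = "All cups",
                        ct_mean = mean(tab$ct_mean),
                        ct_sd = mean(tab$ct_sd),
                        cmm_mean = mean(tab$cmm_mean),
                        cmm_sd = mean(tab$cmm_sd),
                        difference = mean(tab$ct_mean) - mean(tab$cmm_mean),
                        stringsAsFactors = FALSE)
  rbind(tab, all_row)
}

#' Creep estimate from soak controls
#'
#' Soak-control cups are immersed but never loaded, so any apparent
#' penetration they show is creep (plus soak), not wear. The creep estimate
#' is the arithmetic mean of the control cups' penetration values.
#'
#' @param control_penetrations penetration values of the soak-control cups,
#'   mm (at least one)
#' @return mean creep, mm
#' @export
estimate_creep <- function(control_penetrations) {
  v <- as.numeric(control_penetrations)
  if (length(v) < 1L) abort_parse("need at least one soak-control value")
  mean(v)
}

#' Bland-Altman plot
#'
#' Difference against mean with the bias line and the ±1.96 SD limits of
#' agreement, the customary graphical normality/agreement check.
#'
#' @param summary an `agreement_summary` from [bland_altman]
#' @param xlab,ylab,main plot annotation
#' @param ... passed to [graphics::plot]
#' @return the summary, invisibly
#' @export
plot_bland_altman <- function(summary, xlab = "Mean of methods",
                              ylab = "Difference (A - B)",
                              main = "Bland-Altman", ...) {
  stopifnot(inherits(summary, "agreement_summary"))
  graphics::plot(summary$means, summary$differences, xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(summary$differences, summary$loa_low,
                                summary$loa_high)), ...)
  graphics::abline(h = summary$mean_difference, lty = 1)
  graphics::abline(h = c(summary$loa_low, summary$loa_high), lty = 2)
  invisible(summary)
}
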