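# Clinical outcome statistics: Cockcroft-Gault creatinine clearance, renal
# categorization, Wilson score intervals, and unstratified Newcombe
# (method 10) confidence intervals for differences of proportions.

#' Cockcroft-Gault creatinine clearance
#'
#' Sex-specific Cockcroft-Gault estimate from actual body weight:
#' `CrCl = (140 - age) * weight / (72 * scr)`, multiplied by 0.85 for
#' females. Vectorized over all arguments.
#'
#' @param age years, `18 <= age < 140`.
#' @param weight actual body weight (kg), > 0.
#' @param scr serum creatinine (mg/dL), > 0.
#' @param sex `"male"` or `"female"` (recycled).
#' @return CrCl in mL/min.
#' @examples
#' cockcroft_gault(50, 72, 1.0, "male")    # 90
#' cockcroft_gault(50, 72, 1.0, "female")  # 76.5
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  if (any(!is.finite(age)) || any(age < 18)) stop_input("age must be >= 18 years")
  if (any(age >= 140)) stop_input("age must be < 140 years")
  if (any(weight <= 0)) stop_input("weight must be positive")
  if (any(scr <= 0)) stop_input("serum creatinine must be positive")
  crcl <- (140 - age) * weight / (72 * scr)
  crcl * ifelse(sex == "female", 0.85, 1)
}

#' Categorize renal function by CrCl
#'
#' `[80, 130]` mL/min is normal renal function (130 inclusive), anything
#' above 130 is augmented renal clearance (ARC), and below 80 is `"other"`
#' (excluded from the outcome comparisons).
#'
#' @param crcl CrCl in mL/min, >= 0; vectorized.
#' @return factor with levels `normal`, `ARC`, `other`.
#' @examples
#' categorize_renal(c(79.9, 80, 130, 130.01))
#' @export
categorize_renal <- function(crcl) {
  if (any(!is.finite(crcl)) || any(crcl < 0)) stop_input("crcl must be >= 0")
  factor(ifelse(crcl > 130, "ARC", ifelse(crcl >= 80, "normal", "other")),
         levels = c("normal", "ARC", "other"))
}

#' Wilson score interval for a proportion
#'
#' Closed-form Wilson interval, the inversion of the score test at
#' `z = qnorm(1 - alpha/2)` (1.959964 for 95%).
#'
#' @param x successes, `0 <= x <= n`.
#' @param n group size, >= 1.
#' @param alpha two-sided level, default 0.05.
#' @return numeric `c(low, high)` on the proportion scale.
#' @examples
#' round(wilson_interval(66, 88), 4)  # 0.6504 0.8287
#' @export
wilson_interval <- function(x, n, alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(n) || n < 1 || x < 0 || x > n) {
    stop_input("need 0 <= x <= n with n >= 1")
  }
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = (centre - half) / den, high = (centre + half) / den)
}

#' Newcombe (method 10) confidence interval for a difference of proportions
#'
#' Unstratified Newcombe hybrid-score interval for `p1 - p2`: with Wilson
#' bounds `(l1, u1)` and `(l2, u2)`,
#' `CI = [d - sqrt((p1-l1)^2 + (u2-p2)^2), d + sqrt((u1-p1)^2 + (p2-l2)^2)]`.
#' The difference and bounds are reported in percentage points; displayed
#' values round half-away-from-zero to 1 decimal, unrounded values are kept.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @param alpha two-sided level, default 0.05.
#' @param label comparison label.
#' @param direction text recorded for the direction, default
#'   `"g1_minus_g2"`.
#' @return list of class `ct_comparison` with `diff_pp`, `ci_low_pp`,
#'   `ci_high_pp` (unrounded percentage points), the display-rounded
#'   `diff_display`, `ci_low_display`, `ci_high_display`, and the inputs.
#' @examples
#' cmp <- newcombe_diff_ci(66, 88, 49, 70)
#' c(cmp$diff_display, cmp$ci_low_display, cmp$ci_high_display)  # 5.0 -8.7 19.0
#' @export
newcombe_diff_ci <- function(x1, n1, x2, n2, alpha = 0.05, label = "",
                             direction = "g1_minus_g2") {
  if (any(c(n1, n2) < 1)) stop_input("group sizes must be >= 1")
  w1 <- wilson_interval(x1, n1, alpha)
  w2 <- wilson_interval(x2, n2, alpha)
  p1 <- x1 / n1
  p2 <- x2 / n2
  d <- p1 - p2
  lo <- d - sqrt((p1 - w1[["low"]])^2 + (w2[["high"]] - p2)^2)
  hi <- d + sqrt((w1[["high"]] - p1)^2 + (p2 - w2[["low"]])^2)
  structure(list(
    label = label, direction = direction,
    x1 = x1, n1 = n1, x2 = x2, n2 = n2, alpha = alpha,
    p1 = p1, p2 = p2,
    diff_pp = 100 * d, ci_low_pp = 100 * lo, ci_high_pp = 100 * hi,
    diff_display = round_half_away(100 * d),
    ci_low_display = round_half_away(100 * lo),
    ci_high_display = round_half_away(100 * hi)
  ), class = "ct_comparison")
}

#' @export
print.ct_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): %.1f%% vs %.1f%%; diff %.1f pp [%.1f, %.1f]\n",
              if (nzchar(x$label)) x$label else "comparison", x$direction,
              100 * x$p1, 100 * x$p2, x$diff_display, x$ci_low_display,
              x$ci_high_display))
  invisible(x)
}

#' Recover an integer count from a printed 1-decimal percentage
#'
#' Finds the unique `x` in `0..n` whose percentage `100 x/n`, rounded
#' half-away-from-zero to one decimal, equals the printed rate. Integer
#' arithmetic is used so ties are exact. Errors if no count or more than one
#' count is consistent.
#'
#' @param rate_pct printed percentage, one decimal, in `[0, 100]`.
#' @param n denominator, >= 1.
#' @return the recovered integer count.
#' @examples
#' recover_count(17.6, 131)  # 23
#' recover_count(59.4, 96)   # 57
#' @export
recover_count <- function(rate_pct, n) {
  if (!is.numeric(rate_pct) || rate_pct < 0 || rate_pct > 100 || n < 1) {
    stop_input("need 0 <= rate_pct <= 100 and n >= 1")
  }
  n <- as.integer(n)
  target <- as.integer(round(rate_pct * 10))
  x <- 0:n
  # printed tenths of a percent, half away from zero, in exact integers
  tenths <- (2000 * x + n) %/% (2L * n)
  hit <- x[tenths == target]
  if (length(hit) == 0) {
    stop_input(sprintf("no count in 0..%d prints as %.1f%%", n, rate_pct))
  }
  if (length(hit) > 1) {
    stop_input(sprintf("ambiguous: counts {%s} all print as %.1f%% of %d",
                       paste(hit, collapse = ", "), rate_pct, n))
  }
  hit
}

#' Build a table of two-group outcome comparisons
#'
#' Runs [newcombe_diff_ci()] over a counts table. Each row needs `label`,
#' `x1`, `n1`, `x2`, `n2` and optionally `direction`; group 1 minus group 2
#' is always computed, so the caller chooses which group is which. Rows with
#' an empty group are flagged and skipped.
#'
#' @param counts data frame of count rows (e.g. [trial_count_fixtures()]).
#' @param alpha two-sided level, default 0.05.
#' @return data frame with point estimates, unrounded and display-rounded
#'   differences and CI bounds in percentage points.
#' @export
build_outcome_table <- function(counts, alpha = 0.05) {
  need <- c("label", "x1", "n1", "x2", "n2")
  if (!all(need %in% names(counts))) {
    stop_input("counts must have columns ", paste(need, collapse = ", "))
  }
  if (any(counts$x1 > counts$n1) || any(counts$x2 > counts$n2)) {
    bad <- which(counts$x1 > counts$n1 | counts$x2 > counts$n2)
    stop_input("x > n in row(s) ", paste(bad, collapse = ", "))
  }
  keep <- counts$n1 >= 1 & counts$n2 >= 1
  if (any(!keep)) {
    warning("skipping comparison(s) with an empty group: ",
            paste(counts$label[!keep], collapse = ", "))
    counts <- counts[keep, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cc <- newcombe_diff_ci(
      counts$x1[i], counts$n1[i], counts$x2[i], counts$n2[i], alpha = alpha,
      label = counts$label[i],
      direction = if ("direction" %in% names(counts)) counts$direction[i] else "g1_minus_g2")
    data.frame(label = cc$label, direction = cc$direction,
               x1 = cc$x1, n1 = cc$n1, x2 = cc$x2, n2 = cc$n2,
               p1_pct = 100 * cc$p1, p2_pct = 100 * cc$p2,
               diff_pp = cc$diff_pp, ci_low_pp = cc$ci_low_pp,
               ci_high_pp = cc$ci_high_pp,
               diff_display = cc$diff_display,
               ci_low_display = cc$ci_low_display,
               ci_high_display = cc$ci_high_display)
  })
  do.call(rbind, rows)
}
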