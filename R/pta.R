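# Probability of target attainment: per-subject time-above-threshold on the
# free concentration, aggregated over stratified virtual cohorts and
# MIC/threshold grids.

#' PK/PD target definition
#'
#' A target of the form "at least `required_fraction` of the dosing interval
#' with free concentration above `threshold_value`". Defaults used in the
#' analysis: ceftolozane 50% fT>MIC at MIC 4 ug/mL (2-log kill), tazobactam
#' 35% fT>C_T at C_T 1 ug/mL (restores a 1-log kill).
#'
#' @param drug drug label.
#' @param threshold_type `"MIC"` (ceftolozane) or `"C_T"` (tazobactam).
#' @param required_fraction required fraction of the interval, in (0, 1].
#' @param threshold_value threshold concentration (ug/mL), >= 0.
#' @param matrix default matrix the target is evaluated in.
#' @param use_free evaluate on free concentrations (default TRUE).
#' @return object of class `ct_target`.
#' @export
pd_target <- function(drug, threshold_type = c("MIC", "C_T"),
                      required_fraction, threshold_value,
                      matrix = c("plasma", "elf"), use_free = TRUE) {
  threshold_type <- match.arg(threshold_type)
  matrix <- match.arg(matrix)
  if (!is.numeric(required_fraction) || required_fraction <= 0 ||
      required_fraction > 1) {
    stop_input("required_fraction must lie in (0, 1]")
  }
  if (!is.numeric(threshold_value) || threshold_value < 0) {
    stop_input("threshold_value must be >= 0")
  }
  structure(list(drug = drug, threshold_type = threshold_type,
                 required_fraction = required_fraction,
                 threshold_value = threshold_value, matrix = matrix,
                 use_free = isTRUE(use_free)),
            class = "ct_target")
}

#' Default threshold grids (doubling dilutions)
#'
#' MIC grid 0.125-64 ug/mL, threshold-concentration (C_T) grid 0.125-16
#' ug/mL, in doubling dilutions as on a PTA-versus-MIC plot.
#'
#' @param threshold_type `"MIC"` or `"C_T"`.
#' @return ascending numeric vector of thresholds (ug/mL).
#' @export
threshold_grid <- function(threshold_type = c("MIC", "C_T")) {
  threshold_type <- match.arg(threshold_type)
  if (threshold_type == "MIC") 2^seq(-3, 6) else 2^seq(-3, 4)
}

# fraction of [0, tau] a piecewise-linear profile spends strictly above thr;
# crossings are located by linear interpolation within each grid segment
# rather than counting grid points.
time_above_fraction <- function(times, conc, thr) {
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  hi <- pmax(c1, c2)
  lo <- pmin(c1, c2)
  f <- (hi - thr) / pmax(hi - lo, .Machine$double.xmin)
  f[hi <= thr] <- 0
  f[lo > thr] <- 1
  f <- pmin(f, 1)
  sum(f * dt) / (times[length(times)] - times[1])
}

#' Fraction of the dosing interval above a threshold
#'
#' Computes fT>MIC (or fT>C_T): the fraction of `[0, tau]` during which the
#' selected concentration exceeds `threshold`. Crossing times are refined by
#' linear interpolation within grid segments.
#'
#' @param profile a `ct_profile` spanning one steady-state dosing interval.
#' @param threshold threshold concentration (ug/mL), >= 0.
#' @param matrix `"plasma"` or `"elf"`.
#' @param use_free use free (TRUE, default) or total concentrations.
#' @return fraction in `[0, 1]`.
#' @examples
#' p <- pk_parameters(CL = 5.391, V1 = 13, Q = 5, V2 = 6, fu_plasma = 0.79)
#' prof <- plasma_profile_ss(p, dosing_regimen(2000, 1, 8))
#' fraction_time_above(prof, 4)
#' @export
fraction_time_above <- function(profile, threshold,
                                matrix = c("plasma", "elf"), use_free = TRUE) {
  stopifnot(inherits(profile, "ct_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop_input("threshold must be a single number >= 0")
  }
  conc <- profile_column(profile, match.arg(matrix),
                         if (use_free) "free" else "total")
  time_above_fraction(profile$time_h, conc, threshold)
}

#' Does a profile attain a PK/PD target?
#'
#' TRUE iff the fraction of the interval above the target threshold is at
#' least the required fraction. The boundary attains: a fraction of exactly
#' 0.50 meets a 50% target.
#'
#' @param profile a `ct_profile`.
#' @param target a [pd_target()].
#' @param matrix matrix to evaluate in; defaults to the target's.
#' @return logical.
#' @export
attains <- function(profile, target, matrix = target$matrix) {
  stopifnot(inherits(target, "ct_target"))
  fraction_time_above(profile, target$threshold_value, matrix,
                      target$use_free) >= target$required_fraction
}

# total and (optionally) ELF steady-state concentration matrices
# (subjects x times) for an individualized-parameter table
cohort_conc <- function(par, regimen, times, elf_driver = "total",
                        want_elf = TRUE) {
  n <- nrow(par)
  P <- matrix(0, n, length(times))
  E <- if (want_elf) matrix(0, n, length(times)) else NULL
  for (i in seq_len(n)) {
    p <- list(CL = par$CL[i], V1 = par$V1[i], Q = par$Q[i], V2 = par$V2[i],
              k_in = par$k_in[i], k_out = par$k_out[i])
    mt <- macro_terms(p)
    P[i, ] <- ss_conc(mt, regimen$dose_mg, regimen$infusion_h,
                      regimen$interval_h, times)
    if (want_elf) {
      scale <- if (elf_driver == "free") par$fu_plasma[i] else 1
      E[i, ] <- ss_conc(elf_terms(p, mt, scale), regimen$dose_mg,
                        regimen$infusion_h, regimen$interval_h, times)
    }
  }
  list(plasma = P, elf = E)
}

# vectorized time-above fractions for a conc matrix and a threshold grid
time_above_matrix <- function(times, conc, grid) {
  dt <- diff(times)
  tau <- times[length(times)] - times[1]
  C1 <- conc[, -ncol(conc), drop = FALSE]
  C2 <- conc[, -1, drop = FALSE]
  hi <- pmax(C1, C2)
  lo <- pmin(C1, C2)
  span <- pmax(hi - lo, .Machine$double.xmin)
  out <- matrix(0, nrow(conc), length(grid))
  for (j in seq_along(grid)) {
    f <- (hi - grid[j]) / span
    f[hi <= grid[j]] <- 0
    f[lo > grid[j]] <- 1
    f[f > 1] <- 1
    out[, j] <- as.vector(f %*% dt) / tau
  }
  out
}

#' Monte Carlo probability of target attainment
#'
#' For each stratum in the cohort, individualizes PK parameters (covariates
#' plus log-normal IIV), computes each subject's steady-state free
#' concentration profile once, and evaluates attainment across the whole
#' threshold grid in plasma and/or ELF. PTA at a grid value is the fraction
#' of subjects attaining the target there.
#'
#' @param cohort data frame from [sample_stratum()] (one or several strata
#'   row-bound together).
#' @param model a [drug_model()].
#' @param grid ascending threshold grid; default [threshold_grid()] for the
#'   model's target type.
#' @param matrices character subset of `c("plasma", "elf")`.
#' @param times simulation time grid; default [ss_time_grid()] of the
#'   model's regimen.
#' @param seed integer seed; IIV draws use a named substream per drug and
#'   stratum so results are reproducible and stable under extension.
#' @param pneumonia logical, passed to [individualize()].
#' @return data frame of class `ct_pta`: `drug`, `stratum`, `matrix`,
#'   `threshold`, `pta`, `n`, `seed`.
#' @export
simulate_pta <- function(cohort, model, grid = NULL,
                         matrices = c("plasma", "elf"),
                         times = ss_time_grid(model$regimen),
                         seed = NULL, pneumonia = TRUE) {
  stopifnot(inherits(model, "ct_drug_model"))
  if (is.null(cohort) || nrow(cohort) == 0) stop_input("cohort is empty")
  if (is.null(grid)) grid <- threshold_grid(model$target$threshold_type)
  if (any(diff(grid) <= 0)) stop_input("threshold grid must be ascending")
  if (any(grid < 0)) stop_input("thresholds must be >= 0")
  matrices <- match.arg(matrices, several.ok = TRUE)
  want_elf <- "elf" %in% matrices
  out <- list()
  for (st in unique(cohort$stratum)) {
    sub <- cohort[cohort$stratum == st, , drop = FALSE]
    par <- individualize(sub, model$base, model$cov, model$iiv,
                         pneumonia = pneumonia,
                         seed = substream_seed(if (is.null(seed)) 0 else seed,
                                               paste("iiv", model$drug, st)))
    conc <- cohort_conc(par, model$regimen, times, model$elf_driver, want_elf)
    for (m in matrices) {
      fu <- if (m == "plasma") par$fu_plasma else par$fu_elf
      frac <- time_above_matrix(times, conc[[m]] * fu, grid)
      pta <- colMeans(frac >= model$target$required_fraction)
      out[[length(out) + 1L]] <- data.frame(
        drug = model$drug, stratum = st, matrix = m, threshold = grid,
        pta = pta, n = nrow(sub),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("ct_pta", "data.frame")
  res
}

#' Per-subject steady-state exposure metrics for a cohort
#'
#' Computes AUC over one dosing interval (trapezoid) and Cmax for every
#' subject, in plasma and/or ELF, on total or free concentrations.
#'
#' @inheritParams simulate_pta
#' @param quantity `"total"` (default, as in clinical exposure summaries) or
#'   `"free"`.
#' @return data frame: `subject_id`, `crcl_ml_min`, `matrix`, `auc_0_tau`,
#'   `cmax`.
#' @export
cohort_exposures <- function(cohort, model, matrices = c("plasma", "elf"),
                             times = ss_time_grid(model$regimen),
                             quantity = c("total", "free"),
                             seed = NULL, pneumonia = TRUE) {
  stopifnot(inherits(model, "ct_drug_model"))
  if (is.null(cohort) || nrow(cohort) == 0) stop_input("cohort is empty")
  quantity <- match.arg(quantity)
  matrices <- match.arg(matrices, several.ok = TRUE)
  par <- individualize(cohort, model$base, model$cov, model$iiv,
                       pneumonia = pneumonia,
                       seed = substream_seed(if (is.null(seed)) 0 else seed,
                                             paste("iiv", model$drug, "exposure")))
  conc <- cohort_conc(par, model$regimen, times, model$elf_driver,
                      want_elf = "elf" %in% matrices)
  w <- c(diff(times) / 2, 0) + c(0, diff(times) / 2)  # trapezoid weights
  out <- list()
  for (m in matrices) {
    cm <- conc[[m]]
    if (quantity == "free") {
      cm <- cm * (if (m == "plasma") par$fu_plasma else par$fu_elf)
    }
    out[[m]] <- data.frame(
      subject_id = cohort$subject_id, crcl_ml_min = cohort$crcl_ml_min,
      matrix = m, auc_0_tau = as.vector(cm %*% w),
      cmax = apply(cm, 1, max))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Geometric-mean exposure summaries by CrCl bin
#'
#' Groups per-subject exposure values into CrCl bins and reports the
#' geometric mean and geometric percent CV (`100 sqrt(exp(s2_ln) - 1)`,
#' sample variance with n-1 denominator). A single-subject bin reports a
#' geometric CV of 0.
#'
#' @param exposures data frame with columns `crcl_ml_min` and `value_col`
#'   (e.g. from [cohort_exposures()]).
#' @param bins named list of [renal_stratum()] objects; default
#'   [exposure_bins()].
#' @param value_col column to summarize, default `"auc_0_tau"`.
#' @return data frame: `bin`, `n`, `geometric_mean`, `geometric_cv_percent`.
#' @export
summarize_exposures <- function(exposures, bins = exposure_bins(),
                                value_col = "auc_0_tau") {
  if (!all(c("crcl_ml_min", value_col) %in% names(exposures))) {
    stop_input("exposures must have crcl_ml_min and ", value_col, " columns")
  }
  x <- exposures[[value_col]]
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_input("exposure values must be strictly positive")
  }
  rows <- lapply(bins, function(b) {
    inb <- exposures$crcl_ml_min >= b$crcl_low &
      (exposures$crcl_ml_min < b$crcl_high |
         (b$crcl_high >= 312 & exposures$crcl_ml_min <= b$crcl_high))
    if (!any(inb)) {
      return(data.frame(bin = b$label, n = 0L, geometric_mean = NA_real_,
                        geometric_cv_percent = NA_real_))
    }
    g <- geo_stats(x[inb])
    data.frame(bin = b$label, n = g$n, geometric_mean = g$geometric_mean,
               geometric_cv_percent = g$geometric_cv_percent)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
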