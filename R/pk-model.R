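# Closed-form steady-state concentration engine.
#
# The disposition model is linear, so every concentration (central plasma,
# ELF link) is a sum of exponential terms in the unit-dose impulse response.
# For the two-compartment model the macro-constants follow the standard
# algebra:
#   k10 = CL/V1, k12 = Q/V1, k21 = Q/V2
#   alpha + beta = k10 + k12 + k21,  alpha * beta = k10 * k21
#   C_bolus(t) = (D/V1) * [ (alpha-k21)/(alpha-beta) e^{-alpha t}
#                         + (k21-beta)/(alpha-beta) e^{-beta t} ]
# The ELF link compartment obeys dC_E/dt = k_in * C_driver(t) - k_out * C_E,
# which adds, for each plasma term c e^{-l t}, the pair
#   k_in c / (k_out - l) * (e^{-l t} - e^{-k_out t}).
# Repeated 0-order infusions at steady state are handled term-by-term with
# the geometric accumulation factor; all exponent arguments are kept <= 0 so
# nothing overflows even for very fast rate constants.

# (coef, rate) pairs of the plasma unit-dose impulse response
macro_terms <- function(p) {
  k10 <- p$CL / p$V1
  if (p$Q == 0) {
    return(list(coef = 1 / p$V1, rate = k10))
  }
  k12 <- p$Q / p$V1
  k21 <- p$Q / p$V2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if (disc < 1e-12 * alpha) {
    stop_input("degenerate disposition: alpha and beta coincide")
  }
  list(coef = c((alpha - k21) / (p$V1 * (alpha - beta)),
                (k21 - beta) / (p$V1 * (alpha - beta))),
       rate = c(alpha, beta))
}

# (coef, rate) pairs of the ELF unit-dose impulse response; driver_scale is 1
# when the link is driven by total plasma concentration, fu_plasma when driven
# by free concentration.
elf_terms <- function(p, plasma = macro_terms(p), driver_scale = 1) {
  k_out <- p$k_out
  coef <- numeric(0)
  rate <- numeric(0)
  for (i in seq_along(plasma$coef)) {
    l <- plasma$rate[i]
    # guard the removable singularity k_out == l with a relative nudge
    if (abs(k_out - l) < 1e-7 * k_out) k_out <- k_out * (1 + 1e-7)
    a <- driver_scale * p$k_in * plasma$coef[i] / (k_out - l)
    coef <- c(coef, a, -a)
    rate <- c(rate, l, k_out)
  }
  list(coef = coef, rate = rate)
}

# Steady-state concentration for a sum-of-exponentials impulse response under
# repeated zero-order infusion (rate dose/tinf over [0, tinf], period tau).
ss_conc <- function(terms, dose, tinf, tau, times) {
  r0 <- dose / tinf
  out <- numeric(length(times))
  during <- times <= tinf
  for (i in seq_along(terms$coef)) {
    l <- terms$rate[i]
    amp <- terms$coef[i] * r0 / l
    base <- numeric(length(times))
    base[during] <- 1 - exp(-l * times[during])
    base[!during] <- (1 - exp(-l * tinf)) * exp(-l * (times[!during] - tinf))
    # accumulated tails of all previous doses; exponent argument is <= 0
    tail <- (1 - exp(-l * tinf)) * exp(-l * (times - tinf + tau)) /
      (1 - exp(-l * tau))
    out <- out + amp * (base + tail)
  }
  pmax(out, 0)
}

#' Default simulation time grid over one dosing interval
#'
#' Regular grid on `[0, tau]` at `dt` resolution with an exact node at the
#' end of infusion, where Cmax occurs for this model.
#'
#' @param regimen a [dosing_regimen()].
#' @param dt grid resolution (h), default 0.005.
#' @return increasing numeric vector spanning 0 to tau.
#' @export
ss_time_grid <- function(regimen, dt = 0.005) {
  stopifnot(inherits(regimen, "ct_regimen"))
  sort(unique(c(seq(0, regimen$interval_h, by = dt),
                regimen$infusion_h, regimen$interval_h)))
}

check_times <- function(times, tau) {
  if (length(times) < 2 || anyNA(times)) stop_input("time grid must have >= 2 finite values")
  if (any(diff(times) <= 0)) stop_input("time grid must be strictly increasing")
  if (min(times) < 0 || max(times) > tau + 1e-9) {
    stop_input("time grid must lie within [0, tau]")
  }
  times
}

new_profile <- function(times, plasma_total, elf_total, params, regimen) {
  df <- data.frame(
    time_h = times,
    plasma_total = plasma_total,
    plasma_free = params$fu_plasma * plasma_total,
    elf_total = elf_total,
    elf_free = params$fu_elf * elf_total
  )
  structure(df, class = c("ct_profile", "data.frame"),
            params = params, regimen = regimen)
}

#' Steady-state plasma concentration profile
#'
#' Closed-form steady-state total (and free) plasma concentration over one
#' dosing interval for the two-compartment infusion model, by superposition
#' of the within-interval infusion/post-infusion segments with geometric
#' accumulation of earlier doses.
#'
#' @param params a [pk_parameters()].
#' @param regimen a [dosing_regimen()].
#' @param times increasing time grid within `[0, tau]`;
#'   default [ss_time_grid()].
#' @return a `ct_profile` data frame with columns `time_h`, `plasma_total`,
#'   `plasma_free` (`elf_*` columns are `NA`).
#' @examples
#' p <- pk_parameters(CL = 5, V1 = 12, Q = 2, V2 = 6, fu_plasma = 0.79)
#' reg <- dosing_regimen(2000, 1, 8)
#' prof <- plasma_profile_ss(p, reg)
#' max(prof$plasma_total)
#' @export
plasma_profile_ss <- function(params, regimen, times = ss_time_grid(regimen)) {
  stopifnot(inherits(params, "ct_pkpar"), inherits(regimen, "ct_regimen"))
  times <- check_times(times, regimen$interval_h)
  conc <- ss_conc(macro_terms(params), regimen$dose_mg,
                  regimen$infusion_h, regimen$interval_h, times)
  new_profile(times, conc, rep(NA_real_, length(times)), params, regimen)
}

#' Steady-state ELF concentration profile
#'
#' Adds the hypothetical epithelial lining fluid link compartment
#' (`dC_ELF/dt = k_in C_plasma - k_out C_ELF`) at periodic steady state. At
#' steady state the ELF/plasma AUC ratio over a dosing interval equals
#' `k_in/k_out`. By default the link is driven by total plasma
#' concentration; set `driver = "free"` to drive it by free concentration.
#'
#' @inheritParams plasma_profile_ss
#' @param driver `"total"` (default) or `"free"` plasma concentration as the
#'   link input.
#' @return a `ct_profile` data frame with plasma and ELF columns filled.
#' @export
elf_profile_ss <- function(params, regimen, times = ss_time_grid(regimen),
                           driver = c("total", "free")) {
  stopifnot(inherits(params, "ct_pkpar"), inherits(regimen, "ct_regimen"))
  driver <- match.arg(driver)
  times <- check_times(times, regimen$interval_h)
  pl_terms <- macro_terms(params)
  scale <- if (driver == "free") params$fu_plasma else 1
  plasma <- ss_conc(pl_terms, regimen$dose_mg, regimen$infusion_h,
                    regimen$interval_h, times)
  elf <- ss_conc(elf_terms(params, pl_terms, scale), regimen$dose_mg,
                 regimen$infusion_h, regimen$interval_h, times)
  new_profile(times, plasma, elf, params, regimen)
}

#' Apply unbound fractions to a concentration profile
#'
#' Recomputes the free-concentration columns from the totals:
#' `plasma_free = fu_plasma * plasma_total`, `elf_free = fu_elf * elf_total`.
#'
#' @param profile a `ct_profile`.
#' @param params a [pk_parameters()] supplying `fu_plasma` and `fu_elf`;
#'   defaults to the parameters the profile was built with.
#' @return the profile with free columns recomputed.
#' @export
free_profile <- function(profile, params = attr(profile, "params")) {
  stopifnot(inherits(profile, "ct_profile"))
  if (params$fu_plasma <= 0 || params$fu_plasma > 1 ||
      params$fu_elf <= 0 || params$fu_elf > 1) {
    stop_input("unbound fractions must lie in (0, 1]")
  }
  profile$plasma_free <- params$fu_plasma * profile$plasma_total
  profile$elf_free <- params$fu_elf * profile$elf_total
  attr(profile, "params") <- params
  profile
}

profile_column <- function(profile, matrix = c("plasma", "elf"),
                           quantity = c("total", "free")) {
  matrix <- match.arg(matrix)
  quantity <- match.arg(quantity)
  col <- paste(matrix, quantity, sep = "_")
  v <- profile[[col]]
  if (anyNA(v)) stop_input(sprintf("profile has no %s concentrations", matrix))
  v
}

#' Exposure metrics over one dosing interval
#'
#' Trapezoidal AUC over `[0, tau]` and Cmax (grid maximum; the default grid
#' carries an exact node at end of infusion where the peak occurs).
#'
#' @param profile a `ct_profile` spanning a full dosing interval.
#' @param matrix `"plasma"` or `"elf"`.
#' @param quantity `"total"` or `"free"`.
#' @return list of class `ct_exposure`: `auc_0_tau` (ug.h/mL), `cmax`
#'   (ug/mL), `matrix_label`, `quantity`.
#' @examples
#' p <- pk_parameters(CL = 5.391, V1 = 13, Q = 5, V2 = 6)
#' m <- exposure_metrics(plasma_profile_ss(p, dosing_regimen(2000, 1, 8)))
#' m$auc_0_tau  # = dose/CL = 371.0 for linear PK at steady state
#' @export
exposure_metrics <- function(profile, matrix = c("plasma", "elf"),
                             quantity = c("total", "free")) {
  stopifnot(inherits(profile, "ct_profile"))
  matrix <- match.arg(matrix)
  quantity <- match.arg(quantity)
  reg <- attr(profile, "regimen")
  times <- profile$time_h
  check_times(times, reg$interval_h)
  if (length(times) < 20) stop_input("grid too sparse for exposure metrics")
  if (abs(times[1]) > 1e-9 || abs(times[length(times)] - reg$interval_h) > 1e-9) {
    stop_input("profile must span the full dosing interval [0, tau]")
  }
  conc <- profile_column(profile, matrix, quantity)
  auc <- sum(diff(times) * (conc[-1] + conc[-length(conc)]) / 2)
  structure(list(auc_0_tau = auc, cmax = max(conc),
                 matrix_label = matrix, quantity = quantity),
            class = "ct_exposure")
}
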