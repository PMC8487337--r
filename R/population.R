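# Stratified virtual patients: paired weight/CrCl demographics plus
# covariate and inter-individual-variability models that individualize the
# structural PK parameters.

#' Renal function stratum
#'
#' CrCl interval used to stratify the virtual population. Intervals are
#' closed on the left and open on the right, except the terminal cap
#' (312 mL/min) which is inclusive; this convention matters only for
#' labelling since CrCl is sampled continuously.
#'
#' @param label stratum label.
#' @param crcl_low,crcl_high bounds in mL/min, `crcl_low < crcl_high`.
#' @param arc logical: augmented renal clearance stratum?
#' @return object of class `ct_stratum`.
#' @export
renal_stratum <- function(label, crcl_low, crcl_high, arc = crcl_low >= 130) {
  if (!is.numeric(crcl_low) || !is.numeric(crcl_high) || crcl_low < 0 ||
      crcl_low >= crcl_high) {
    stop_input("stratum requires 0 <= crcl_low < crcl_high")
  }
  structure(list(label = label, crcl_low = crcl_low, crcl_high = crcl_high,
                 arc = isTRUE(arc)),
            class = "ct_stratum")
}

#' Canonical PTA strata
#'
#' The four simulation strata: normal renal function 80-130 mL/min and three
#' augmented renal clearance (ARC) strata >130-<180, 180-<210, and >=210
#' capped at 312 mL/min (the upper end observed in the source demographic
#' pool).
#'
#' @return named list of [renal_stratum()] objects.
#' @export
canonical_strata <- function() {
  list(
    `80-130`  = renal_stratum("80-130", 80, 130, arc = FALSE),
    `130-180` = renal_stratum("130-180", 130, 180),
    `180-210` = renal_stratum("180-210", 180, 210),
    `210-312` = renal_stratum("210-312", 210, 312)
  )
}

#' Exposure-summary CrCl bins
#'
#' The alternative binning used for exposure summaries (AUC, Cmax):
#' >=80-<150, >=150-<180, >=180-<210, >=210 (capped at 312).
#'
#' @return named list of [renal_stratum()] objects.
#' @export
exposure_bins <- function() {
  list(
    `80-150`  = renal_stratum("80-150", 80, 150, arc = FALSE),
    `150-180` = renal_stratum("150-180", 150, 180),
    `180-210` = renal_stratum("180-210", 180, 210),
    `210-312` = renal_stratum("210-312", 210, 312)
  )
}

#' Paired weight/CrCl demographic model
#'
#' Body weight is log-normal; CrCl given weight follows a log-scale
#' regression `log(CrCl) = intercept + slope * log(weight/wt_ref) + eps`,
#' `eps ~ N(0, sd)`, preserving the positive weight-CrCl association.
#' Defaults give a median weight of 80 kg with an interquartile range close
#' to 72-90 kg and a wide CrCl span so that every stratum up to 312 mL/min
#' is reachable.
#'
#' @param log_wt_mean,log_wt_sd log-scale mean and sd of weight (kg).
#' @param crcl_intercept log CrCl (mL/min) at the reference weight.
#' @param crcl_slope regression slope on log weight.
#' @param crcl_sd residual sd of log CrCl given weight; >= 0.
#' @param wt_ref reference weight (kg).
#' @return object of class `ct_demo`.
#' @export
demographic_model <- function(log_wt_mean = log(80), log_wt_sd = 0.165,
                              crcl_intercept = log(115), crcl_slope = 0.8,
                              crcl_sd = 0.40, wt_ref = 80) {
  if (crcl_sd < 0 || log_wt_sd < 0) stop_input("standard deviations must be >= 0")
  structure(list(log_wt_mean = log_wt_mean, log_wt_sd = log_wt_sd,
                 crcl_intercept = crcl_intercept, crcl_slope = crcl_slope,
                 crcl_sd = crcl_sd, wt_ref = wt_ref),
            class = "ct_demo")
}

#' Sample a stratified virtual cohort (demographics only)
#'
#' Draws `n` subjects with paired weight and CrCl, the CrCl conditional on
#' weight and truncated to the stratum bounds by inverse-CDF sampling (so no
#' rejection loop and exact determinism under a seed). With `crcl_sd = 0`
#' CrCl is the deterministic regression value, clamped to the stratum.
#'
#' @param stratum a [renal_stratum()].
#' @param n number of subjects, >= 1.
#' @param demo a [demographic_model()].
#' @param seed integer seed (optional but recommended).
#' @return data frame: `subject_id`, `weight_kg`, `crcl_ml_min`, `stratum`.
#' @examples
#' cohort <- sample_stratum(canonical_strata()[["210-312"]], 5,
#'                          demographic_model(), seed = 1)
#' range(cohort$crcl_ml_min)  # within [210, 312]
#' @export
sample_stratum <- function(stratum, n, demo = demographic_model(), seed = NULL) {
  stopifnot(inherits(stratum, "ct_stratum"), inherits(demo, "ct_demo"))
  if (!is.numeric(n) || n < 1) stop_input("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    wt <- exp(stats::rnorm(n, demo$log_wt_mean, demo$log_wt_sd))
    mu <- demo$crcl_intercept + demo$crcl_slope * log(wt / demo$wt_ref)
    lo <- log(stratum$crcl_low)
    hi <- log(stratum$crcl_high)
    if (demo$crcl_sd == 0) {
      crcl <- pmin(pmax(exp(mu), stratum$crcl_low), stratum$crcl_high)
    } else {
      p_lo <- stats::pnorm(lo, mu, demo$crcl_sd)
      p_hi <- stats::pnorm(hi, mu, demo$crcl_sd)
      if (mean(p_hi - p_lo) < 1e-10) {
        stop_input("stratum has (numerically) empty feasible region under this demographic model")
      }
      u <- p_lo + stats::runif(n) * (p_hi - p_lo)
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      crcl <- pmin(pmax(exp(stats::qnorm(u, mu, demo$crcl_sd)),
                        stratum$crcl_low), stratum$crcl_high)
    }
    data.frame(subject_id = seq_len(n), weight_kg = wt, crcl_ml_min = crcl,
               stratum = stratum$label)
  })
}

#' Covariate model on the structural PK parameters
#'
#' CrCl acts on clearance through a power model,
#' `CL = CL_ref * (CrCl/crcl_ref)^cl_crcl_exponent`; weight acts on the
#' volumes through `(WT/wt_ref)^v_weight_exponent`; pneumonia multiplies the
#' volumes and the ELF influx/elimination rate constants.
#'
#' @param crcl_ref reference CrCl (mL/min).
#' @param cl_crcl_exponent power of the CrCl effect on CL.
#' @param wt_ref reference weight (kg).
#' @param v_weight_exponent power of the weight effect on V1 and V2.
#' @param pneumonia_v_multiplier,pneumonia_kin_multiplier,pneumonia_kout_multiplier
#'   multiplicative pneumonia effects (> 0).
#' @return object of class `ct_cov`.
#' @export
covariate_model <- function(crcl_ref = 115, cl_crcl_exponent = 0.75,
                            wt_ref = 80, v_weight_exponent = 1,
                            pneumonia_v_multiplier = 1,
                            pneumonia_kin_multiplier = 1,
                            pneumonia_kout_multiplier = 1) {
  mult <- c(pneumonia_v_multiplier, pneumonia_kin_multiplier,
            pneumonia_kout_multiplier)
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop_input("pneumonia multipliers must be positive")
  }
  if (!is.finite(cl_crcl_exponent) || !is.finite(v_weight_exponent)) {
    stop_input("covariate exponents must be finite")
  }
  structure(list(crcl_ref = crcl_ref, cl_crcl_exponent = cl_crcl_exponent,
                 wt_ref = wt_ref, v_weight_exponent = v_weight_exponent,
                 pneumonia_v_multiplier = pneumonia_v_multiplier,
                 pneumonia_kin_multiplier = pneumonia_kin_multiplier,
                 pneumonia_kout_multiplier = pneumonia_kout_multiplier),
            class = "ct_cov")
}

#' Inter-individual variability model
#'
#' Log-normal random effects: each parameter is multiplied by `exp(eta)`
#' with `eta ~ N(0, omega^2)`, drawn once per subject. Omegas are log-scale
#' standard deviations; 0 disables variability on that parameter.
#'
#' @param omega_cl,omega_v1,omega_q,omega_v2,omega_kin,omega_kout log-scale
#'   sds, all >= 0.
#' @return object of class `ct_iiv`.
#' @export
iiv_model <- function(omega_cl = 0, omega_v1 = 0, omega_q = 0, omega_v2 = 0,
                      omega_kin = 0, omega_kout = 0) {
  om <- c(omega_cl, omega_v1, omega_q, omega_v2, omega_kin, omega_kout)
  if (any(!is.finite(om)) || any(om < 0)) stop_input("omegas must be >= 0")
  structure(list(omega_cl = omega_cl, omega_v1 = omega_v1, omega_q = omega_q,
                 omega_v2 = omega_v2, omega_kin = omega_kin,
                 omega_kout = omega_kout),
            class = "ct_iiv")
}

#' Individualized PK parameters for a cohort
#'
#' Applies the covariate model to each subject's CrCl and weight and draws
#' one log-normal random effect per subject and parameter:
#' `CL_i = CL_ref (CrCl_i/crcl_ref)^e exp(eta_CL)`,
#' `V_i = V_ref (WT_i/wt_ref)^e (pneumonia multiplier) exp(eta_V)`, with the
#' ELF rate constants scaled by their pneumonia multipliers.
#'
#' @param subjects data frame from [sample_stratum()] (needs `weight_kg`,
#'   `crcl_ml_min`).
#' @param base typical-value [pk_parameters()] at the reference covariates.
#' @param cov a [covariate_model()].
#' @param iiv an [iiv_model()]; all-zero omegas give the deterministic
#'   covariate prediction.
#' @param pneumonia logical; the simulated population has pneumonia by
#'   default.
#' @param seed integer seed for the random-effect draws.
#' @return data frame: `subject_id` plus columns `CL`, `V1`, `Q`, `V2`,
#'   `k_in`, `k_out`, `fu_plasma`, `fu_elf`.
#' @export
individualize <- function(subjects, base, cov = covariate_model(),
                          iiv = iiv_model(), pneumonia = TRUE, seed = NULL) {
  stopifnot(inherits(base, "ct_pkpar"), inherits(cov, "ct_cov"),
            inherits(iiv, "ct_iiv"))
  need <- c("weight_kg", "crcl_ml_min")
  if (!all(need %in% names(subjects))) {
    stop_input("subjects must have weight_kg and crcl_ml_min columns")
  }
  if (any(subjects$weight_kg <= 0) || any(subjects$crcl_ml_min <= 0)) {
    stop_input("covariate values must be positive")
  }
  n <- nrow(subjects)
  with_seed(seed, {
    eta <- function(om) if (om > 0) stats::rnorm(n, 0, om) else numeric(n)
    e_cl <- eta(iiv$omega_cl); e_v1 <- eta(iiv$omega_v1)
    e_q <- eta(iiv$omega_q); e_v2 <- eta(iiv$omega_v2)
    e_ki <- eta(iiv$omega_kin); e_ko <- eta(iiv$omega_kout)
    pv <- if (pneumonia) cov$pneumonia_v_multiplier else 1
    pki <- if (pneumonia) cov$pneumonia_kin_multiplier else 1
    pko <- if (pneumonia) cov$pneumonia_kout_multiplier else 1
    wt_f <- (subjects$weight_kg / cov$wt_ref)^cov$v_weight_exponent
    data.frame(
      subject_id = if ("subject_id" %in% names(subjects)) subjects$subject_id else seq_len(n),
      CL = base$CL * (subjects$crcl_ml_min / cov$crcl_ref)^cov$cl_crcl_exponent * exp(e_cl),
      V1 = base$V1 * wt_f * pv * exp(e_v1),
      Q = base$Q * exp(e_q),
      V2 = base$V2 * wt_f * pv * exp(e_v2),
      k_in = base$k_in * pki * exp(e_ki),
      k_out = base$k_out * pko * exp(e_ko),
      fu_plasma = base$fu_plasma,
      fu_elf = base$fu_elf
    )
  })
}

#' Bundle a drug's simulation inputs
#'
#' Collects the typical parameters, covariate model, IIV model, regimen,
#' PK/PD target and ELF driver convention for one drug.
#'
#' @param drug drug label.
#' @param base [pk_parameters()] typical values.
#' @param cov [covariate_model()].
#' @param iiv [iiv_model()].
#' @param regimen [dosing_regimen()].
#' @param target [pd_target()].
#' @param elf_driver `"total"` or `"free"` plasma concentration driving the
#'   ELF link.
#' @return object of class `ct_drug_model`.
#' @export
drug_model <- function(drug, base, cov, iiv, regimen, target,
                       elf_driver = c("total", "free")) {
  structure(list(drug = drug, base = base, cov = cov, iiv = iiv,
                 regimen = regimen, target = target,
                 elf_driver = match.arg(elf_driver)),
            class = "ct_drug_model")
}

#' Read a drug model from a YAML parameter file
#'
#' Parameter sets are versioned YAML files with blocks `regimen`,
#' `parameters`, `covariates`, `iiv`, `target` (see the packaged
#' `ceftolozane.yaml` / `tazobactam.yaml` under `extdata` for the documented
#' layout and units).
#'
#' @param path YAML file path.
#' @return a [drug_model()].
#' @export
read_drug_model <- function(path) {
  if (!file.exists(path)) stop_input("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  for (blk in c("drug", "regimen", "parameters", "covariates", "iiv", "target")) {
    if (is.null(y[[blk]])) stop_input("parameter file missing block: ", blk)
  }
  drug_model(
    drug = y$drug,
    base = do.call(pk_parameters, y$parameters),
    cov = do.call(covariate_model, y$covariates),
    iiv = do.call(iiv_model, y$iiv),
    regimen = dosing_regimen(y$regimen$dose_mg, y$regimen$infusion_h,
                             y$regimen$interval_h, drug = y$drug),
    target = pd_target(drug = y$drug,
                       threshold_type = y$target$threshold_type,
                       required_fraction = y$target$required_fraction,
                       threshold_value = y$target$threshold_value),
    elf_driver = if (is.null(y$elf_driver)) "total" else y$elf_driver
  )
}

#' Default calibrated drug models
#'
#' The shipped ceftolozane and tazobactam parameter sets. The published
#' population-PK estimates behind the original simulations are not public;
#' these sets are calibrated so that typical-subject steady-state exposures
#' and their population spread approximate the observed plasma/ELF exposure
#' summaries in ventilated nosocomial pneumonia (AUC0-8 geometric means of
#' roughly 371 and 61.9 ug.h/mL in the 80-150 mL/min bin for ceftolozane and
#' tazobactam; ELF/plasma AUC ratios about 0.54 and 0.40).
#'
#' @return named list with elements `ceftolozane` and `tazobactam`.
#' @export
default_drug_models <- function() {
  list(
    ceftolozane = read_drug_model(system.file("extdata", "ceftolozane.yaml",
                                              package = "ctpta", mustWork = TRUE)),
    tazobactam = read_drug_model(system.file("extdata", "tazobactam.yaml",
                                             package = "ctpta", mustWork = TRUE))
  )
}
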