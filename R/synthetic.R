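# Synthetic trial cohorts and packaged outcome-count fixtures.
#
# The restricted trial data cannot be redistributed; the generator below
# produces participant tables with the statistical structure the outcome
# analysis assumes (CrCl arising mechanistically from age/weight/sex/serum
# creatinine through Cockcroft-Gault, binary outcomes at category-specific
# rates), and the fixtures package the published counts.

#' Specification for a synthetic trial cohort
#'
#' Demographics are drawn per arm: truncated-normal age (>= 18), log-normal
#' weight, sex-specific log-normal serum creatinine. CrCl is then computed
#' with [cockcroft_gault()] - never sampled directly - so the renal
#' categories emerge mechanistically. Defaults put roughly a third of
#' subjects in each of normal/ARC/other, echoing the source trial's
#' 35%/29% normal/ARC split, and use its observed outcome rates.
#'
#' @param n_per_arm subjects per arm.
#' @param arms arm labels.
#' @param age_mean,age_sd age distribution (years), truncated at >= 18.
#' @param prop_male probability of male sex.
#' @param log_wt_mean,log_wt_sd log-scale weight (kg) parameters.
#' @param scr_meanlog named vector (male, female) of log-scale serum
#'   creatinine medians (mg/dL).
#' @param scr_sdlog log-scale sd of serum creatinine.
#' @param rates nested list `rates[[arm]][[category]]` with elements
#'   `mortality`, `clinical_cure`, `micro_cure`, all in `[0, 1]`; categories
#'   `normal`, `ARC`, `other`.
#' @param seed integer seed.
#' @return object of class `ct_cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = 1000,
                        arms = c("CT", "meropenem"),
                        age_mean = 54, age_sd = 16, prop_male = 0.75,
                        log_wt_mean = log(80), log_wt_sd = 0.18,
                        scr_meanlog = c(male = log(0.95), female = log(0.80)),
                        scr_sdlog = 0.45,
                        rates = default_outcome_rates(),
                        seed = 20210) {
  if (n_per_arm < 1) stop_input("n_per_arm must be >= 1")
  for (arm in names(rates)) {
    for (cat in names(rates[[arm]])) {
      r <- unlist(rates[[arm]][[cat]])
      if (any(r < 0 | r > 1)) stop_input("outcome rates must lie in [0, 1]")
    }
  }
  if (!all(arms %in% names(rates))) stop_input("rates must cover every arm")
  structure(list(n_per_arm = as.integer(n_per_arm), arms = arms,
                 age_mean = age_mean, age_sd = age_sd, prop_male = prop_male,
                 log_wt_mean = log_wt_mean, log_wt_sd = log_wt_sd,
                 scr_meanlog = scr_meanlog, scr_sdlog = scr_sdlog,
                 rates = rates, seed = seed),
            class = "ct_cohort_spec")
}

#' Default outcome rates for the synthetic cohort
#'
#' The published 28-day all-cause mortality, clinical cure and per-patient
#' microbiologic cure rates by arm and renal category (ITT/mITT); the
#' `other` (CrCl < 80) category, which the published comparison excludes,
#' reuses the normal-function rates.
#'
#' @return nested list keyed by arm then renal category.
#' @export
default_outcome_rates <- function() {
  ct_norm <- list(mortality = 0.176, clinical_cure = 0.573, micro_cure = 0.722)
  mero_norm <- list(mortality = 0.203, clinical_cure = 0.593, micro_cure = 0.750)
  list(
    CT = list(normal = ct_norm,
              ARC = list(mortality = 0.177, clinical_cure = 0.594, micro_cure = 0.714),
              other = ct_norm),
    meropenem = list(normal = mero_norm,
                     ARC = list(mortality = 0.177, clinical_cure = 0.575, micro_cure = 0.700),
                     other = mero_norm)
  )
}

#' Generate a synthetic participant table
#'
#' Draws demographics per the spec, computes CrCl via [cockcroft_gault()],
#' derives the renal category, and draws each binary outcome Bernoulli at
#' the arm- and category-specific rate. Demographics and outcomes use
#' independent named seed substreams, so enlarging one stage does not
#' perturb the other. If some category receives no subjects a warning is
#' raised and that category is simply empty.
#'
#' @param spec a [cohort_spec()].
#' @return data frame: `id`, `arm`, `age`, `sex`, `weight_kg`,
#'   `serum_creatinine`, `crcl_ml_min`, `renal_category`, `itt`, `mitt`,
#'   `ce`, `mortality_day28`, `clinical_cure_toc`, `micro_cure_toc`.
#' @examples
#' head(generate_cohort(cohort_spec(n_per_arm = 50)))
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "ct_cohort_spec"))
  n_tot <- spec$n_per_arm * length(spec$arms)
  demo <- with_seed(substream_seed(spec$seed, "demographics"), {
    age <- spec$age_mean + spec$age_sd * stats::rnorm(n_tot)
    while (any(bad <- age < 18 | age >= 140)) {           # truncation by redraw
      age[bad] <- spec$age_mean + spec$age_sd * stats::rnorm(sum(bad))
    }
    sex <- ifelse(stats::runif(n_tot) < spec$prop_male, "male", "female")
    wt <- exp(stats::rnorm(n_tot, spec$log_wt_mean, spec$log_wt_sd))
    scr <- exp(stats::rnorm(n_tot, spec$scr_meanlog[sex], spec$scr_sdlog))
    data.frame(age = age, sex = sex, weight_kg = wt, serum_creatinine = scr)
  })
  demo$crcl_ml_min <- cockcroft_gault(demo$age, demo$weight_kg,
                                      demo$serum_creatinine, demo$sex)
  demo$renal_category <- categorize_renal(demo$crcl_ml_min)
  out <- cbind(
    data.frame(id = seq_len(n_tot),
               arm = rep(spec$arms, each = spec$n_per_arm)),
    demo)
  empty <- setdiff(c("normal", "ARC"), unique(as.character(out$renal_category)))
  if (length(empty)) {
    warning("no synthetic subjects in renal category: ",
            paste(empty, collapse = ", "))
  }
  with_seed(substream_seed(spec$seed, "outcomes"), {
    rate_of <- function(outcome) {
      mapply(function(a, cat) spec$rates[[a]][[cat]][[outcome]],
             out$arm, as.character(out$renal_category))
    }
    out$itt <- TRUE
    out$mitt <- stats::runif(n_tot) < 0.75   # analysis-population plumbing
    out$ce <- stats::runif(n_tot) < 0.65
    out$mortality_day28 <- stats::runif(n_tot) < rate_of("mortality")
    out$clinical_cure_toc <- stats::runif(n_tot) < rate_of("clinical_cure")
    out$micro_cure_toc <- stats::runif(n_tot) < rate_of("micro_cure")
  })
  out
}

#' Packaged outcome-count fixtures
#'
#' The published two-group outcome counts, one row per comparison:
#' microbiologic cure carries the explicitly printed n/N values; mortality
#' and clinical cure counts are recovered from the printed 1-decimal rates
#' and group sizes via [recover_count()] and are tagged `recovered` in the
#' source columns. `direction` records which group is group 1, i.e. the
#' orientation that reproduces each printed difference. The printed
#' difference and CI bounds travel with each row for golden checks; `note`
#' flags the single printed bound that is not reproducible from its counts.
#'
#' @return data frame of fixture rows.
#' @export
trial_count_fixtures <- function() {
  path <- system.file("extdata", "outcome_counts.csv", package = "ctpta",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate a participant table into comparison counts
#'
#' Counts successes by renal category within one arm and population flag,
#' oriented per `direction`.
#'
#' @param records participant data frame from [generate_cohort()] (or a CSV
#'   with the same columns).
#' @param arm arm label to subset.
#' @param outcome outcome column name.
#' @param population population flag column (`itt`, `mitt`, `ce`).
#' @param direction `"normal_minus_arc"` or `"arc_minus_normal"`.
#' @param label row label.
#' @return one-row data frame suitable for [build_outcome_table()].
#' @export
participant_counts <- function(records, arm, outcome,
                               population = "itt",
                               direction = c("normal_minus_arc",
                                             "arc_minus_normal"),
                               label = paste(arm, outcome, sep = "_")) {
  direction <- match.arg(direction)
  sub <- records[records$arm == arm & records[[population]] &
                   records$renal_category %in% c("normal", "ARC"), ,
                 drop = FALSE]
  cnt <- function(cat) {
    g <- sub[sub$renal_category == cat, outcome]
    c(x = sum(g), n = length(g))
  }
  nn <- cnt("normal")
  aa <- cnt("ARC")
  if (direction == "normal_minus_arc") {
    data.frame(label = label, x1 = nn[["x"]], n1 = nn[["n"]],
               x2 = aa[["x"]], n2 = aa[["n"]], direction = direction)
  } else {
    data.frame(label = label, x1 = aa[["x"]], n1 = aa[["n"]],
               x2 = nn[["x"]], n2 = nn[["n"]], direction = direction)
  }
}
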