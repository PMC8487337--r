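#' Intravenous dosing regimen
#'
#' Repeated zero-order (constant-rate) infusion schedule. The default for
#' ceftolozane/tazobactam 3 g in nosocomial pneumonia is a 1-h infusion every
#' 8 h (ceftolozane 2000 mg, tazobactam 1000 mg).
#'
#' @param dose_mg dose per administration (mg), > 0.
#' @param infusion_h infusion duration (h), in (0, interval].
#' @param interval_h dosing interval tau (h), > 0.
#' @param drug drug label.
#' @return object of class `ct_regimen`.
#' @examples
#' dosing_regimen(2000, 1, 8, "ceftolozane")
#' @export
dosing_regimen <- function(dose_mg, infusion_h, interval_h, drug = "drug") {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1 || !is.finite(dose_mg) || dose_mg <= 0) {
    stop_input("dose_mg must be a single positive number")
  }
  if (!is.numeric(interval_h) || interval_h <= 0) stop_input("interval_h must be positive")
  if (!is.numeric(infusion_h) || infusion_h <= 0 || infusion_h > interval_h) {
    stop_input("infusion_h must satisfy 0 < infusion_h <= interval_h")
  }
  structure(list(dose_mg = dose_mg, infusion_h = infusion_h,
                 interval_h = interval_h, drug = drug),
            class = "ct_regimen")
}

#' Structural pharmacokinetic parameters
#'
#' Two-compartment disposition with first-order elimination from the central
#' compartment, plus a hypothetical epithelial lining fluid (ELF) link
#' compartment with first-order influx (`k_in`) from plasma and first-order
#' elimination (`k_out`). `Q = 0` gives the one-compartment limit. Protein
#' binding enters only through the unbound fractions: by default 21% bound in
#' plasma for ceftolozane (`fu_plasma = 0.79`), 30% for tazobactam
#' (`fu_plasma = 0.70`), and 0% in ELF for both (`fu_elf = 1`).
#'
#' @param CL clearance (L/h).
#' @param V1 central volume (L).
#' @param Q intercompartmental clearance (L/h), >= 0.
#' @param V2 peripheral volume (L); ignored when `Q = 0`.
#' @param k_in ELF influx rate constant (1/h).
#' @param k_out ELF elimination rate constant (1/h).
#' @param fu_plasma unbound fraction in plasma, in (0, 1].
#' @param fu_elf unbound fraction in ELF, in (0, 1].
#' @return object of class `ct_pkpar`.
#' @examples
#' pk_parameters(CL = 5.391, V1 = 13, Q = 5, V2 = 6,
#'               k_in = 0.4, k_out = 0.75, fu_plasma = 0.79)
#' @export
pk_parameters <- function(CL, V1, Q = 0, V2 = 1, k_in = 1, k_out = 1,
                          fu_plasma = 1, fu_elf = 1) {
  num1 <- function(x, nm, lo = 0, lo_ok = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (if (lo_ok) x < lo else x <= lo)) {
      stop_input(sprintf("%s must be a single finite number %s %g",
                         nm, if (lo_ok) ">=" else ">", lo))
    }
    x
  }
  p <- list(
    CL = num1(CL, "CL"), V1 = num1(V1, "V1"),
    Q = num1(Q, "Q", lo = 0, lo_ok = TRUE), V2 = num1(V2, "V2"),
    k_in = num1(k_in, "k_in"), k_out = num1(k_out, "k_out"),
    fu_plasma = num1(fu_plasma, "fu_plasma"), fu_elf = num1(fu_elf, "fu_elf")
  )
  if (p$fu_plasma > 1 || p$fu_elf > 1) stop_input("unbound fractions must lie in (0, 1]")
  structure(p, class = "ct_pkpar")
}

#' @export
print.ct_regimen <- function(x, ...) {
  cat(sprintf("<%s regimen> %g mg, %g-h infusion every %g h\n",
              x$drug, x$dose_mg, x$infusion_h, x$interval_h))
  invisible(x)
}

#' @export
print.ct_pkpar <- function(x, ...) {
  cat(sprintf("<PK parameters> CL %.3g L/h, V1 %.3g L, Q %.3g L/h, V2 %.3g L\n",
              x$CL, x$V1, x$Q, x$V2))
  cat(sprintf("  ELF link k_in %.3g /h, k_out %.3g /h; fu plasma %.2f, ELF %.2f\n",
              x$k_in, x$k_out, x$fu_plasma, x$fu_elf))
  invisible(x)
}
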