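# Independent oracles and small generators used across the suite.

# Brute-force ODE oracle: integrate the full compartment system (central,
# peripheral, ELF) from rest through enough dosing intervals to reach
# periodic steady state, then report the last interval. Independent of the
# closed-form engine.
ode_ss_profile <- function(p, reg, times, rtol = 1e-10) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  r0 <- reg$dose_mg / reg$infusion_h
  deriv <- function(t, y, parms) {
    inp <- if (t %% reg$interval_h < reg$infusion_h) r0 else 0
    C1 <- y[1] / p$V1
    C2 <- if (p$Q > 0) y[2] / p$V2 else 0
    list(c(inp - p$CL * C1 - p$Q * C1 + p$Q * C2,
           p$Q * C1 - p$Q * C2,
           p$k_in * C1 - p$k_out * y[3]))
  }
  # slowest system rate decides how many intervals "steady" needs
  k10 <- p$CL / p$V1
  beta <- if (p$Q > 0) {
    k12 <- p$Q / p$V1; k21 <- p$Q / p$V2
    s <- k10 + k12 + k21
    (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  } else k10
  slow <- min(beta, p$k_out)
  n_int <- max(25, ceiling(35 / (slow * reg$interval_h)))
  t0 <- (n_int - 1) * reg$interval_h
  tt <- sort(unique(c(seq(0, t0, length.out = 200), t0 + times)))
  sol <- deSolve::lsoda(c(0, 0, 0), tt, deriv, NULL, rtol = rtol,
                        atol = rtol * reg$dose_mg / p$V1,
                        maxsteps = 1e6, hmax = reg$infusion_h / 4)
  idx <- match(t0 + times, sol[, 1])
  list(plasma = sol[idx, 2] / p$V1, elf = sol[idx, 4])
}

# random drug-like parameter sets for property tests
random_pk_parameters <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    pk_parameters(
      CL = runif(1, 2, 20), V1 = runif(1, 8, 30),
      Q = runif(1, 1, 8), V2 = runif(1, 4, 30),
      k_in = runif(1, 0.05, 1), k_out = runif(1, 0.1, 2),
      fu_plasma = runif(1, 0.5, 1), fu_elf = 1)
  }))
}

# Wilson endpoints by root-finding on the score equation
# (phat - p)^2 = z^2 p (1 - p) / n  -- independent of the closed form.
wilson_by_root <- function(x, n, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  phat <- x / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # at x = 0 (x = n) the trivial root sits at the boundary itself, so the
  # non-trivial endpoint is bracketed away from it
  lo <- if (x == 0) 0 else
    uniroot(f, c(1e-15, if (x == n) 1 - 1e-15 else phat), tol = 1e-14)$root
  hi <- if (x == n) 1 else
    uniroot(f, c(if (x == 0) 1e-15 else phat, 1 - 1e-15), tol = 1e-14)$root
  c(low = lo, high = hi)
}

# trapezoid AUC on an arbitrary grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# profile constructor shortcut for synthetic test profiles
make_profile <- function(times, plasma, elf = rep(NA_real_, length(times)),
                         params = pk_parameters(CL = 1, V1 = 1),
                         regimen = dosing_regimen(1, 1, max(times))) {
  ctpta:::new_profile(times, plasma, elf, params, regimen)
}
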