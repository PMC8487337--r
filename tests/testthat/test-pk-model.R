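test_that("one-compartment limit matches the closed-form steady-state identity", {
  # Q = 0: end-of-infusion concentration is
  # (D/(Tinf*CL)) * (1 - e^{-k Tinf}) / (1 - e^{-k tau})
  p <- pk_parameters(CL = 5, V1 = 12, Q = 0)
  reg <- dosing_regimen(2000, 1, 8)
  k <- p$CL / p$V1
  expected <- (reg$dose_mg / (reg$infusion_h * p$CL)) *
    (1 - exp(-k * reg$infusion_h)) / (1 - exp(-k * reg$interval_h))
  prof <- plasma_profile_ss(p, reg, times = c(0, 0.5, 1, 2, 8))
  expect_equal(prof$plasma_total[prof$time_h == 1], expected, tolerance = 1e-12)
})

test_that("steady-state plasma AUC equals dose/CL (linear-PK conservation)", {
  reg <- dosing_regimen(2000, 1, 8)
  p <- pk_parameters(CL = 5.391, V1 = 18, Q = 7, V2 = 21.6)
  m <- exposure_metrics(plasma_profile_ss(p, reg))
  expect_equal(m$auc_0_tau, 2000 / 5.391, tolerance = 1e-3)  # 371.0
  expect_equal(m$auc_0_tau, 371.0, tolerance = 1e-3)

  m2 <- exposure_metrics(plasma_profile_ss(
    pk_parameters(CL = 16.1, V1 = 28, Q = 7, V2 = 28), dosing_regimen(1000, 1, 8)))
  expect_equal(m2$auc_0_tau, 1000 / 16.1, tolerance = 1e-3)  # ~62.1
})

test_that("closed-form profiles agree with stiff ODE integration to steady state", {
  skip_if_not_installed("deSolve")
  reg <- dosing_regimen(2000, 1, 8)
  times <- seq(0, 8, by = 0.1)
  # the spec-style example set, checked tightly
  p <- pk_parameters(CL = 5, V1 = 12, Q = 2, V2 = 6, k_in = 0.3, k_out = 0.6)
  cf <- elf_profile_ss(p, reg, times)
  od <- ode_ss_profile(p, reg, times)
  expect_lt(max(abs(cf$plasma_total - od$plasma)) / max(od$plasma), 1e-6)
  expect_lt(max(abs(cf$elf_total - od$elf)) / max(od$elf), 1e-6)
  # random draws (the full 100-draw sweep runs in the acceptance suite)
  for (p in random_pk_parameters(10, seed = 11)) {
    cf <- elf_profile_ss(p, reg, times)
    od <- ode_ss_profile(p, reg, times)
    expect_lt(max(abs(cf$plasma_total - od$plasma)) / max(od$plasma), 1e-6)
    expect_lt(max(abs(cf$elf_total - od$elf)) / max(od$elf), 1e-6)
  }
})

test_that("ELF link obeys the steady-state AUC ratio k_in/k_out", {
  reg <- dosing_regimen(2000, 1, 8)
  # k_in = k_out: ELF AUC equals plasma AUC
  p <- pk_parameters(CL = 5.391, V1 = 18, Q = 7, V2 = 21.6, k_in = 0.4, k_out = 0.4)
  prof <- elf_profile_ss(p, reg)
  expect_equal(exposure_metrics(prof, "elf")$auc_0_tau,
               exposure_metrics(prof, "plasma")$auc_0_tau, tolerance = 1e-3)
  # ratio 0.5 with plasma AUC 371.0 -> ELF AUC 185.5
  p <- pk_parameters(CL = 5.391, V1 = 18, Q = 7, V2 = 21.6, k_in = 0.35, k_out = 0.7)
  expect_equal(exposure_metrics(elf_profile_ss(p, reg), "elf")$auc_0_tau,
               185.5, tolerance = 1e-3)
})

test_that("fast ELF kinetics converge to the quasi-equilibrium profile", {
  # k_out large with k_in/k_out fixed: C_ELF -> (k_in/k_out) * C_plasma
  reg <- dosing_regimen(2000, 1, 8)
  p <- pk_parameters(CL = 5, V1 = 12, Q = 2, V2 = 6, k_in = 50, k_out = 100)
  prof <- elf_profile_ss(p, reg)
  expect_lt(max(abs(prof$elf_total - 0.5 * prof$plasma_total)) /
              max(prof$plasma_total), 0.01)
})

test_that("steady-state profiles are periodic and respond monotonically to CL", {
  reg <- dosing_regimen(2000, 1, 8)
  for (p in random_pk_parameters(20, seed = 7)) {
    prof <- elf_profile_ss(p, reg)
    expect_true(all(prof$plasma_total >= 0))
    expect_lt(abs(prof$plasma_total[1] - prof$plasma_total[nrow(prof)]) /
                max(prof$plasma_total), 1e-6)
    expect_lt(abs(prof$elf_total[1] - prof$elf_total[nrow(prof)]) /
                max(prof$elf_total), 1e-6)
  }
  cls <- c(2, 4, 8, 16)
  res <- sapply(cls, function(cl) {
    m <- exposure_metrics(plasma_profile_ss(
      pk_parameters(CL = cl, V1 = 15, Q = 5, V2 = 10), reg))
    c(m$auc_0_tau, m$cmax)
  })
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("free concentrations apply the unbound fractions", {
  times <- seq(0, 8, by = 0.5)
  p <- pk_parameters(CL = 1, V1 = 1, fu_plasma = 0.79, fu_elf = 1)
  prof <- make_profile(times, rep(100, length(times)), rep(50, length(times)), params = p)
  expect_equal(unique(prof$plasma_free), 79)   # 21% plasma binding
  expect_equal(unique(prof$elf_free), 50)      # 0% ELF binding
  # tazobactam: 30% bound in plasma
  taz <- free_profile(prof, pk_parameters(CL = 1, V1 = 1, fu_plasma = 0.70))
  expect_equal(unique(taz$plasma_free), 70)
  expect_equal(free_profile(prof, pk_parameters(CL = 1, V1 = 1))$plasma_free,
               prof$plasma_total)
  expect_error(pk_parameters(CL = 1, V1 = 1, fu_plasma = 1.2), "unbound")
})

test_that("exposure metrics handle flat profiles and reject bad grids", {
  times <- seq(0, 8, by = 0.25)
  prof <- make_profile(times, rep(7, length(times)), rep(7, length(times)))
  m <- exposure_metrics(prof)
  expect_equal(m$auc_0_tau, 56)
  expect_equal(m$cmax, 7)
  # Cmax of the one-compartment profile equals the closed-form end-of-infusion value
  p <- pk_parameters(CL = 5, V1 = 12, Q = 0)
  reg <- dosing_regimen(2000, 1, 8)
  k <- p$CL / p$V1
  cmax <- (reg$dose_mg / (reg$infusion_h * p$CL)) *
    (1 - exp(-k * reg$infusion_h)) / (1 - exp(-k * reg$interval_h))
  expect_equal(exposure_metrics(plasma_profile_ss(p, reg))$cmax, cmax,
               tolerance = 1e-10)
  expect_error(plasma_profile_ss(p, reg, times = c(3, 2, 1)), "increasing")
  expect_error(plasma_profile_ss(p, reg, times = numeric(0)), "time grid")
  expect_error(plasma_profile_ss(p, reg, times = c(0, 4, 9)), "tau")
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_parameters(CL = -1, V1 = 10), "CL")
  expect_error(pk_parameters(CL = 1, V1 = 0), "V1")
  expect_error(dosing_regimen(0, 1, 8), "dose")
  expect_error(dosing_regimen(100, 9, 8), "infusion_h")
})
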