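test_that("fraction of time above a threshold handles trivial bounds", {
  p <- pk_parameters(CL = 5.391, V1 = 18, Q = 7, V2 = 21.6, fu_plasma = 0.79)
  prof <- plasma_profile_ss(p, dosing_regimen(2000, 1, 8))
  expect_equal(fraction_time_above(prof, 0), 1)
  expect_equal(fraction_time_above(prof, max(prof$plasma_free) * 1.01), 0)
  expect_error(fraction_time_above(prof, -1), ">= 0")
})

test_that("crossing times are refined by interpolation, not grid counting", {
  # triangular profile with analytically known crossings: rises 0 -> 10 over
  # [0, 4], falls back to 0 over [4, 8]; above 2.5 between t = 1 and t = 7
  times <- seq(0, 8, by = 0.5)
  tri <- ifelse(times <= 4, 2.5 * times, 2.5 * (8 - times))
  prof <- make_profile(times, tri)
  expect_equal(fraction_time_above(prof, 2.5, use_free = FALSE), 6 / 8,
               tolerance = 1e-12)
  # even with a coarse grid whose nodes miss the crossing at c = 6.25
  expect_equal(fraction_time_above(prof, 6.25, use_free = FALSE), 3 / 8,
               tolerance = 1e-12)
})

test_that("exponential-decay crossing matches the closed form and a dense grid", {
  # one-compartment, t1/2 = 2 h (k = 0.3466), free end-of-infusion conc 32
  # over a 24-h interval so the accumulation residual is negligible: free
  # conc crosses 4 at t = 1 + ln(32/4)/k = 7.0 h
  k <- 0.3466
  fu <- 0.8
  reg <- dosing_regimen(1000, 1, 24)
  V1 <- 1000 * (1 - exp(-k)) / (k * 1 * (32 / fu) * (1 - exp(-24 * k)))
  p <- pk_parameters(CL = k * V1, V1 = V1, Q = 0, fu_plasma = fu)
  prof <- plasma_profile_ss(p, reg)
  eoi <- prof$plasma_free[prof$time_h == 1]
  expect_equal(eoi, 32, tolerance = 1e-6)
  got <- fraction_time_above(prof, 4)
  # rising-phase crossing at -ln(1 - 0.125(1-e^-k))/k, decay crossing at 7 h
  t_up <- -log(1 - (4 / 32) * (1 - exp(-k))) / k
  expect_equal(got, (1 + log(32 / 4) / k - t_up) / 24, tolerance = 5e-3)
  dense <- plasma_profile_ss(p, reg, times = ss_time_grid(reg, 0.0005))
  expect_lt(abs(got - fraction_time_above(dense, 4)), 0.005)  # < 0.5 pp
})

test_that("target attainment uses >= at the required-fraction boundary", {
  times <- seq(0, 8, by = 0.1)
  # free plasma conc 10 for exactly half the interval, then 1
  conc <- ifelse(times < 4, 10, 1)
  conc[times == 4] <- 1
  prof <- make_profile(times, conc)
  tgt <- pd_target("ceftolozane", "MIC", 0.50, 4)
  f <- fraction_time_above(prof, 4)
  expect_equal(f, (3.9 + 0.1 * 6 / 9) / 8, tolerance = 1e-9)
  expect_true(attains(make_profile(c(0, 4, 4.0001, 8), c(10, 10, 1, 1)), tgt))
  # just under the requirement fails
  tgt2 <- pd_target("tazobactam", "C_T", 0.35, 4)
  prof3 <- make_profile(c(0, 2.79, 2.7901, 8), c(10, 10, 1, 1))
  expect_false(attains(prof3, tgt2))  # 0.3488 < 0.35
})

test_that("PTA curves are monotone, bounded, and hit both asymptotes", {
  models <- default_drug_models()
  coh <- rbind(
    sample_stratum(canonical_strata()[["80-130"]], 150, demographic_model(), seed = 2),
    sample_stratum(canonical_strata()[["210-312"]], 150, demographic_model(), seed = 3))
  for (m in models) {
    grid <- c(1e-9, threshold_grid(m$target$threshold_type), 1e6)
    res <- simulate_pta(coh, m, grid = grid, seed = 5)
    expect_true(all(res$pta >= 0 & res$pta <= 1))
    for (st in unique(res$stratum)) {
      for (mx in c("plasma", "elf")) {
        p <- res$pta[res$stratum == st & res$matrix == mx]
        expect_true(all(diff(p) <= 0))
        expect_equal(p[1], 1)                  # threshold -> 0
        expect_equal(p[length(p)], 0)          # threshold -> infinity
      }
    }
  }
})

test_that("PTA is deterministic under a seed and jitters within binomial noise", {
  m <- default_drug_models()$tazobactam
  coh <- sample_stratum(canonical_strata()[["130-180"]], 400,
                        demographic_model(), seed = 31)
  a <- simulate_pta(coh, m, grid = c(0.5, 1, 2), seed = 101)
  b <- simulate_pta(coh, m, grid = c(0.5, 1, 2), seed = 101)
  expect_identical(a, b)
  c2 <- simulate_pta(coh, m, grid = c(0.5, 1, 2), seed = 202)
  expect_lt(max(abs(a$pta - c2$pta)), 0.06)
  expect_error(simulate_pta(coh[0, ], m), "empty")
  expect_error(simulate_pta(coh, m, grid = c(2, 1)), "ascending")
})

test_that("with omegas off, fT>MIC is non-increasing in CrCl", {
  m <- default_drug_models()$ceftolozane
  m$iiv <- iiv_model()
  crcls <- c(85, 110, 140, 170, 200, 230, 260, 290, 312)
  subj <- data.frame(subject_id = seq_along(crcls), weight_kg = 80,
                     crcl_ml_min = crcls, stratum = "sweep")
  par <- individualize(subj, m$base, m$cov, m$iiv, seed = 1)
  fr <- sapply(seq_len(nrow(par)), function(i) {
    p <- pk_parameters(par$CL[i], par$V1[i], par$Q[i], par$V2[i],
                       par$k_in[i], par$k_out[i], par$fu_plasma[i], par$fu_elf[i])
    fraction_time_above(plasma_profile_ss(p, m$regimen), 4)
  })
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("exposure summaries report log-normal geometric moments by bin", {
  expect_equal(summarize_exposures(
    data.frame(crcl_ml_min = 100, auc_0_tau = 5))$geometric_mean[1], 5)
  expect_equal(summarize_exposures(
    data.frame(crcl_ml_min = 100, auc_0_tau = 5))$geometric_cv_percent[1], 0)
  e3 <- data.frame(crcl_ml_min = rep(100, 3), auc_0_tau = rep(exp(1), 3))
  s3 <- summarize_exposures(e3)
  expect_equal(s3$geometric_mean[1], exp(1))
  expect_equal(s3$geometric_cv_percent[1], 0)
  # 10,000 draws from log-normal(ln 371, 0.52): gm ~ 371, gcv ~ 55.6%
  x <- withr::with_seed(13, rlnorm(10000, log(371), 0.52))
  s <- summarize_exposures(data.frame(crcl_ml_min = 100, auc_0_tau = x))
  expect_equal(s$geometric_mean[1], 371, tolerance = 0.02)
  expect_equal(s$geometric_cv_percent[1], 100 * sqrt(exp(0.52^2) - 1),
               tolerance = 0.05)
  expect_error(summarize_exposures(
    data.frame(crcl_ml_min = 100, auc_0_tau = -1)), "positive")
})

test_that("cohort exposures match single-subject profiles", {
  m <- default_drug_models()$ceftolozane
  m$iiv <- iiv_model()  # deterministic
  coh <- sample_stratum(canonical_strata()[["80-130"]], 5,
                        demographic_model(), seed = 21)
  ex <- cohort_exposures(coh, m, matrices = "plasma")
  par <- individualize(coh, m$base, m$cov, m$iiv, seed = 1)
  p1 <- pk_parameters(par$CL[1], par$V1[1], par$Q[1], par$V2[1],
                      par$k_in[1], par$k_out[1], par$fu_plasma[1], par$fu_elf[1])
  m1 <- exposure_metrics(plasma_profile_ss(p1, m$regimen))
  expect_equal(ex$auc_0_tau[1], m1$auc_0_tau, tolerance = 1e-10)
  expect_equal(ex$cmax[1], m1$cmax, tolerance = 1e-10)
  expect_equal(ex$auc_0_tau[1], m$regimen$dose_mg / par$CL[1], tolerance = 1e-3)
})
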