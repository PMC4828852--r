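test_that("cohort simulation is bit-identical under a fixed seed", {
  cfg <- tiny_config(n = 25, seed = 11, miss_rest = 0.02, miss_stress = 0.05)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(tiny_config(n = 25, seed = 12, miss_rest = 0.02,
                                    miss_stress = 0.05))
  expect_false(identical(a$segments$value, c2$segments$value))
})

test_that("cohort has the configured shape and internal consistency", {
  coh <- simulate_cohort(tiny_config(n = 40, seed = 2))
  expect_s3_class(coh, "dse_cohort")
  expect_equal(nrow(coh$patients), 40)
  # 12 segments x 13 parameters x 2 phases per patient
  expect_equal(nrow(coh$segments), 40 * 12 * 13 * 2)
  key <- with(coh$segments, paste(patient_id, segment, parameter, phase))
  expect_equal(anyDuplicated(key), 0)
  p <- coh$patients
  expect_equal(p$any_stenosis, p$LAD | p$LCX | p$RCA)
  expect_true(all(p$wmsi_rest >= 1 & p$wmsi_rest <= 4))
  expect_true(all(p$wmsi_stress >= 1 & p$wmsi_stress <= 4))
  # diseased patients show the larger stress-induced WMSI increment
  d <- delta_wmsi(p$wmsi_rest, p$wmsi_stress)
  expect_gt(mean(d[p$any_stenosis]), mean(d[!p$any_stenosis]))
})

test_that("prevalence and missingness match configuration within sampling error", {
  cfg <- cohort_config(n_patients = 10000, prevalence_any = 0.503,
                       effect_size = 0.5, missing_rate_rest = 0.021,
                       missing_rate_stress = 0.050, seed = 31)
  coh <- simulate_cohort(cfg)
  p_hat <- mean(coh$patients$any_stenosis)
  expect_lt(abs(p_hat - 0.503), 3 * sqrt(0.503 * 0.497 / 10000))

  at_stress <- coh$segments$phase == "stress"
  n_cells <- sum(at_stress)
  miss_stress <- mean(is.na(coh$segments$value[at_stress]))
  expect_lt(abs(miss_stress - 0.050), 3 * sqrt(0.05 * 0.95 / n_cells))
  miss_rest <- mean(is.na(coh$segments$value[!at_stress]))
  expect_lt(abs(miss_rest - 0.021), 3 * sqrt(0.021 * 0.979 / n_cells))
  # every diseased patient has at least one stenotic vessel
  d <- coh$patients[coh$patients$any_stenosis, ]
  expect_true(all(d$LAD | d$LCX | d$RCA))
})

test_that("missing_rate = 0 yields complete phases; effect_size = 0 yields null differences", {
  coh0 <- simulate_cohort(tiny_config(n = 400, effect = 0, seed = 5))
  expect_false(anyNA(coh0$segments$value))
  # null construction: diseased vs healthy stress means agree within MC error
  s <- coh0$segments[coh0$segments$phase == "stress" &
                       coh0$segments$parameter == "systolic_strain", ]
  lab <- coh0$patients$any_stenosis[match(s$patient_id, coh0$patients$patient_id)]
  tt <- t.test(s$value[lab], s$value[!lab])
  expect_gt(tt$p.value, 0.001)
})

test_that("ischemic shifts go in the physiological direction, stress phase only", {
  cfg <- tiny_config(n = 300, effect = 1.5, seed = 8)
  coh <- simulate_cohort(cfg)
  par_tab <- dse_parameters()
  lab <- coh$patients$LAD[match(coh$segments$patient_id,
                                coh$patients$patient_id)]
  in_lad <- territory_of(coh$segments$segment) == "LAD"
  for (pm in c("systolic_strain", "s_velocity", "time_to_s")) {
    dirn <- par_tab$direction[par_tab$parameter == pm]
    sel <- coh$segments$parameter == pm & in_lad
    at_stress <- coh$segments$phase == "stress"
    d_stress <- mean(coh$segments$value[sel & at_stress & lab]) -
      mean(coh$segments$value[sel & at_stress & !lab])
    expect_gt(d_stress * dirn, 0)
    d_rest <- mean(coh$segments$value[sel & !at_stress & lab]) -
      mean(coh$segments$value[sel & !at_stress & !lab])
    expect_lt(abs(d_rest), abs(d_stress) / 2)  # no effect injected at rest
  }
})

test_that("territory map is total, conventional and overridable", {
  expect_equal(territory_of("apical septal"), "LAD")
  expect_equal(territory_of("basal inferior"), "RCA")
  expect_equal(territory_of("mid lateral"), "LCX")
  all_t <- territory_of(dse_segments())
  expect_setequal(unique(all_t), c("LAD", "LCX", "RCA"))
  expect_length(all_t, 12)
  expect_error(territory_of("mid posterior"), "unknown segment")
  custom <- stats::setNames(rep("RCA", 12), dse_segments())
  expect_equal(territory_of("apical septal", map = custom), "RCA")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "positive integer")
  expect_error(cohort_config(prevalence_any = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(missing_rate_stress = -0.1), "\\[0, 1\\]")
  expect_error(cohort_config(effect_size = Inf), "finite")
  expect_error(cohort_config(vessel_probs = c(LAD = 0.5, LCX = 0.5)),
               "vessel_probs")
  expect_error(cohort_config(noise_sd_by_param = c(bogus = 1)), "unknown")
})
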