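test_that("logistic function matches its definition", {
  expect_equal(logistic_phi(0), 0.5)
  expect_equal(logistic_phi(2), exp(2) / (1 + exp(2)))
  expect_equal(logistic_phi(2), 0.880797077977882, tolerance = 1e-12)
  y <- c(-3, -0.5, 0.1, 4)
  expect_equal(logistic_phi(y) + logistic_phi(-y), rep(1, 4))
  # overflow-safe at extreme arguments
  expect_equal(logistic_phi(800), 1)
  expect_equal(logistic_phi(-800), 0)
})

test_that("rescaled response follows its two branches and the zero rules", {
  expect_equal(rescale_value(0, 0, 1, 0.5), 0)        # p = T exactly
  expect_equal(rescale_value(0, 0, 1, 0.25), 1 / 3)   # (0.5-0.25)/(1-0.25)
  expect_equal(rescale_value(NA, 0, 1, 0.25), 0)      # missing -> 0
  # sub-threshold branch: p = 0.5 below T = 0.8 -> (0.8-0.5)/0.8
  expect_equal(rescale_value(0, 0, 1, 0.8), 0.3 / 0.8)
  expect_error(rescale_value(0, 0, 1, 1.2), "strictly in")
  expect_error(rescale_value(0, 0, 1, 0), "strictly in")
})

test_that("rescaled response matches the independent oracle on a grid", {
  grid <- expand.grid(
    b0 = c(-2, 0, 1.5), b1 = c(-1.2, 0.7, 2),
    t = c(0.1, 0.5, 0.9), x = c(-5, -0.3, 0, 0.3, 5, NA)
  )
  got <- mapply(function(x, b0, b1, t) rescale_value(x, b0, b1, t),
                grid$x, grid$b0, grid$b1, grid$t)
  want <- mapply(function(x, b0, b1, t) oracle_rescale(x, b0, b1, t),
                 grid$x, grid$b0, grid$b1, grid$t)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rescaled response has range [0,1], continuity and saturation limits", {
  set.seed(55)
  n <- 20000
  b0 <- runif(n, -3, 3); b1 <- runif(n, -3, 3)
  t <- runif(n, 0.02, 0.98); x <- rnorm(n, 0, 4)
  r <- rescale_value(x, b0, b1, t)
  expect_true(all(r >= 0 & r <= 1))
  # continuity at the branch boundary: p -> T from both sides gives r -> 0
  tt <- 0.37
  x_at <- (qlogis(tt) - 0.2) / 1.3
  eps <- 1e-9
  expect_lt(rescale_value(x_at + eps, 0.2, 1.3, tt), 1e-6)
  expect_lt(rescale_value(x_at - eps, 0.2, 1.3, tt), 1e-6)
  # both tails saturate at 1 (distance-from-threshold semantics)
  expect_equal(rescale_value(1e4, 0, 1, 0.3), 1)
  expect_equal(rescale_value(-1e4, 0, 1, 0.3), 1)
  # strictly monotone in |p - T| within each branch
  xs <- seq(x_at + 0.01, x_at + 2, length.out = 50)
  expect_true(all(diff(rescale_value(xs, 0.2, 1.3, tt)) > 0))
})

test_that("strict-fidelity branch compares the linear predictor to T", {
  # lp = 0.4 > T = 0.3 while p = 0.599 > T too: branches agree
  expect_equal(rescale_value(0.4, 0, 1, 0.3, strict_fidelity = TRUE),
               (plogis(0.4) - 0.3) / 0.7)
  # lp = -0.5 < T = 0.3 but p = 0.378 > T: the two readings diverge
  strict <- rescale_value(-0.5, 0, 1, 0.3, strict_fidelity = TRUE)
  default <- rescale_value(-0.5, 0, 1, 0.3)
  expect_equal(strict, (0.3 - plogis(-0.5)) / 0.3)
  expect_equal(default, (plogis(-0.5) - 0.3) / 0.7)
  expect_false(isTRUE(all.equal(strict, default)))
})

test_that("build_matrix yields a complete [0,1] matrix matching hand evaluation", {
  coh <- fixture_cohort("missing-heavy")
  scr <- data.frame(
    feature_id = c("systolic_strain|apical septal|stress",
                   "s_velocity|basal anterior|rest"),
    parameter = c("systolic_strain", "s_velocity"),
    segment = c("apical septal", "basal anterior"),
    phase = c("stress", "rest"),
    beta0 = c(1.2, -0.4), beta1 = c(0.3, 0.9),
    threshold = c(0.4, 0.6), stringsAsFactors = FALSE
  )
  R <- build_matrix(coh, scr)
  expect_equal(dim(R), c(10, 2))
  expect_false(anyNA(R))
  expect_true(all(R >= 0 & R <= 1))
  # cell-by-cell against the oracle
  X <- dsemodel:::cohort_covariates(coh)
  for (k in 1:2) {
    want <- vapply(X[, scr$feature_id[k]], oracle_rescale, numeric(1),
                   b0 = scr$beta0[k], b1 = scr$beta1[k], t = scr$threshold[k])
    expect_equal(unname(R[, k]), unname(want), tolerance = 1e-12)
  }
  # a fully missing covariate rescales to an all-zero column
  coh$segments$value[coh$segments$segment == "apical septal" &
                       coh$segments$parameter == "systolic_strain" &
                       coh$segments$phase == "stress"] <- NA
  R2 <- build_matrix(coh, scr)
  expect_equal(unname(R2[, 1]), rep(0, 10))
  expect_error(build_matrix(coh, scr[0, ]), "no screened features")
})
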