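test_that("bidirectional AIC stepwise agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(303)
  for (i in 1:8) {
    n <- 120
    k <- 6
    X <- matrix(runif(n * k), n, k, dimnames = list(NULL, paste0("c", 1:k)))
    y <- rbinom(n, 1, plogis(-1 + 3 * X[, 2] + 2 * X[, 5]))
    if (length(unique(y)) < 2) next
    mine <- sort(dsemodel:::aic_stepwise(X, y))
    df <- data.frame(X, .y = y)
    null_fit <- glm(.y ~ 1, family = binomial(), data = df)
    ref <- MASS::stepAIC(
      null_fit, scope = list(lower = ~1, upper = reformulate(colnames(X), ".y")),
      direction = "both", trace = 0
    )
    ref_sel <- sort(match(setdiff(names(coef(ref)), "(Intercept)"), colnames(X)))
    expect_equal(as.integer(mine), as.integer(ref_sel))
  }
})

test_that("zero screened features give an intercept-only prevalence model", {
  coh <- simulate_cohort(tiny_config(n = 40, effect = 0, seed = 21))
  scr <- coh |> screen_all("any", alpha = 0)
  m <- stepwise_fit(matrix(numeric(0), 40, 0), coh$patients$any_stenosis,
                    screened = scr, endpoint = "any")
  expect_length(m$selected, 0)
  prev <- mean(coh$patients$any_stenosis)
  expect_equal(unname(plogis(m$coefficients[["(Intercept)"]])), prev)
  pr <- predict_proba(m, coh)
  expect_equal(unname(pr), rep(prev, 40))
})

test_that("an exactly duplicated feature is retained only once", {
  set.seed(23)
  n <- 200
  x <- runif(n)
  y <- rbinom(n, 1, plogis(-2 + 4 * x))
  X <- cbind(a = x, b = x, c = runif(n))
  sel <- dsemodel:::aic_stepwise(X, y)
  expect_equal(sum(sel %in% c(1, 2)), 1)
})

test_that("stepwise selection is a subset of screened features with finite coefficients", {
  coh <- simulate_cohort(tiny_config(n = 100, effect = 1, seed = 24,
                                     miss_stress = 0.05))
  m <- suppressWarnings(fit_endpoint_model(coh, "any"))
  expect_s3_class(m, "dse_model")
  expect_true(all(m$selected %in% m$screened$feature_id))
  expect_true(all(is.finite(m$coefficients)))
  expect_named(m$coefficients[1], "(Intercept)")
})

test_that("predicted probabilities match hand evaluation and handle missingness", {
  coh <- fixture_cohort("complete")
  sub <- data.frame(
    feature_id = c("systolic_strain|apical septal|stress",
                   "time_to_s|mid anterior|stress"),
    parameter = c("systolic_strain", "time_to_s"),
    segment = c("apical septal", "mid anterior"),
    phase = c("stress", "stress"),
    beta0 = c(2.1, -3.0), beta1 = c(0.25, 0.02),
    threshold = c(0.45, 0.55), stringsAsFactors = FALSE
  )
  m <- dsemodel:::new_dse_model(
    endpoint = "any", screened = as.data.frame(sub),
    selected = sub$feature_id,
    coefficients = c("(Intercept)" = -0.7,
                     stats::setNames(c(1.4, -2.2), sub$feature_id)),
    decision_threshold = 0.5, criterion = "aic", strict_fidelity = FALSE
  )
  pr <- predict_proba(m, coh)
  X <- dsemodel:::cohort_covariates(coh)
  for (i in seq_len(nrow(coh$patients))) {
    r1 <- oracle_rescale(X[i, sub$feature_id[1]], sub$beta0[1], sub$beta1[1],
                         sub$threshold[1])
    r2 <- oracle_rescale(X[i, sub$feature_id[2]], sub$beta0[2], sub$beta1[2],
                         sub$threshold[2])
    expect_equal(unname(pr[i]), plogis(-0.7 + 1.4 * r1 - 2.2 * r2),
                 tolerance = 1e-12)
  }
  expect_true(all(pr > 0 & pr < 1))
  # all covariates missing -> phi(intercept)
  coh_na <- coh
  coh_na$segments$value <- NA_real_
  pr_na <- predict_proba(m, coh_na)
  expect_equal(unname(pr_na), rep(plogis(-0.7), nrow(coh$patients)))
})

test_that("classification uses the >= threshold convention", {
  coh <- fixture_cohort("complete")
  m <- dsemodel:::new_dse_model(
    "any", data.frame(), character(0),
    c("(Intercept)" = qlogis(0.7)), 0.5, "aic", FALSE
  )
  expect_true(all(classify(m, coh)))                       # 0.7 >= 0.5
  m$coefficients[["(Intercept)"]] <- qlogis(0.5)
  expect_true(all(classify(m, coh)))                       # tie -> positive
  expect_false(any(classify(m, coh, decision_threshold = 1.0)))
})

test_that("single-class outcomes are rejected", {
  X <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(stepwise_fit(X, rep(1, 10), screened = data.frame()),
               "both outcome classes")
})

test_that("run_study evaluates all methods on both cohorts", {
  train <- simulate_cohort(tiny_config(n = 80, effect = 1.2, seed = 31))
  valid <- simulate_cohort(tiny_config(n = 60, effect = 1.2, seed = 32,
                                       group = "validation"))
  st <- suppressWarnings(run_study(train, valid))
  expect_s3_class(st, "dse_study")
  expect_setequal(names(st$models), c("any", "LAD", "LCX", "RCA"))
  expect_equal(nrow(st$report), 10)  # 5 methods x 2 groups
  expect_setequal(unique(st$report$method),
                  c("visual", "model_patient", "model_LAD", "model_LCX",
                    "model_RCA"))
  # confusion counts per row total the cohort size
  tot <- rowSums(st$report[c("tp", "fp", "tn", "fn")])
  expect_equal(tot, rep(c(80, 60), each = 5))
  # identical cohorts as train and validation give identical rows
  st2 <- suppressWarnings(run_study(train, train))
  r <- st2$report
  test_rows <- r[r$group == "test", -1]
  val_rows <- r[r$group == "validation", -1]
  rownames(test_rows) <- rownames(val_rows) <- NULL
  expect_equal(test_rows, val_rows)
})

test_that("schema mismatches between cohorts are rejected", {
  a <- simulate_cohort(tiny_config(n = 10, seed = 41))
  b <- simulate_cohort(tiny_config(n = 10, seed = 42, group = "validation"))
  b$segments <- b$segments[b$segments$parameter != "s_velocity", ]
  expect_error(run_study(a, b), "different segment/parameter schemas")
})

test_that("parameter recovery: a single strong feature keeps a stable positive weight", {
  coefs <- c()
  for (seed in 1:5) {
    set.seed(700 + seed)
    n <- 500
    y <- rbinom(n, 1, 0.5)
    # informative column on the rescaled [0,1] scale, 1.5-SD class shift,
    # plus three null columns
    R <- cbind(
      inf = pmin(1, pmax(0, rnorm(n, 0.35 + 0.3 * y, 0.2))),
      matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("f", 2:4)))
    )
    scrd <- data.frame(feature_id = colnames(R))
    m <- stepwise_fit(R, y, screened = scrd, endpoint = "any")
    expect_true("inf" %in% m$selected)
    coefs <- c(coefs, m$coefficients[["inf"]])
  }
  expect_true(all(coefs > 0))
  expect_lt(stats::sd(coefs) / mean(coefs), 0.5)
})
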