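# Linear-predictor model: design coding, fitting, nesting and reporting.

design_fixture <- function() {
  rows <- c(
    "r1,ES,rural,female,40,centre,3,3",       # reference profile
    "r2,ES,urban,male,50,extreme_right,4,4",  # age one sd above mean
    "r3,ES,rural,female,30,left,2,2",
    "r4,ES,urban,male,40,right,3,3",
    "r5,ES,rural,female,40,centre,3,3")       # duplicate of r1's covariates
  ds <- read_survey(write_tiny_survey(rows = rows), tiny_schema())
  build_design(ds, "q_support", "ES")
}

test_that("design rows code reference levels, dummies and standardized age", {
  d <- design_fixture()
  X <- d$X
  expect_equal(colnames(X),
               c("intercept", "location_urban", "sex_male", "age_std",
                 "pol_extreme_left", "pol_left", "pol_right",
                 "pol_extreme_right"))
  # ages are 40,50,30,40,40: mean 40, sd sqrt(50)
  expect_equal(d$age_center, 40)
  expect_equal(d$age_scale, sqrt(50))
  expect_equal(mean(X[, "age_std"]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, "age_std"]), 1, tolerance = 1e-12)
  # rural female at mean age, centre politics: all non-intercept terms zero
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0, 0))
  # urban male, extreme right, age above mean
  expect_equal(unname(X[2, c("location_urban", "sex_male",
                             "pol_extreme_right")]), c(1, 1, 1))
  expect_gt(X[2, "age_std"], 0)
  # at most one politics dummy per row; dummies are 0/1
  pol <- X[, grepl("^pol_", colnames(X))]
  expect_true(all(pol %in% c(0, 1)))
  expect_true(all(rowSums(pol) <= 1))
  # identical covariates give identical rows
  expect_equal(X[1, ], X[5, ])
})

test_that("rows with missing answers or missing politics are dropped and counted", {
  rows <- c("r1,ES,rural,female,40,centre,3,3",
            "r2,ES,urban,male,50,,4,4",        # missing politics
            "r3,ES,rural,female,30,left,,2",   # missing answer
            "r4,ES,urban,male,45,right,DK,3")  # DK kept, counted separately
  ds <- read_survey(write_tiny_survey(rows = rows), tiny_schema())
  d <- build_design(ds, "q_support", "ES")
  expect_equal(d$n_dropped, 2)
  expect_equal(nrow(d$X), 1)          # only r1 contributes an ordinal row
  expect_equal(d$encoded$dk_count, 1)
  expect_equal(d$encoded$n_total, 2)
})

test_that("a stratum with politics entirely missing is refused", {
  rows <- c("r1,ES,rural,female,40,,3,3",
            "r2,ES,urban,male,50,,4,4")
  ds <- read_survey(write_tiny_survey(rows = rows), tiny_schema())
  expect_error(build_design(ds, "q_support", "ES"), "missing")
})

test_that("constant design columns are flagged as unidentifiable", {
  set.seed(8)
  tr <- covariate_truth(alpha = 3, sigma = 1)
  q <- question_spec("q", 5)
  scn <- scenario(data.frame(country = "XX", w_rural = 0.5,
                             n_rural = 200, n_urban = 0),   # rural only
                  questions = list(q = list(spec = q, truth = tr)), seed = 2)
  ds <- simulate_survey(scn)
  d <- build_design(ds, "q", "XX")
  expect_warning(
    fit <- fit_covariate(d, control = quick_ctl(1, chains = 2, iters = 400,
                                                burn = 200)),
    "location_urban")
  expect_true("location_urban" %in% fit$unidentifiable)
})

test_that("the intercept-only covariate model nests the single-group model", {
  # every respondent sits at the reference profile, so the linear predictor
  # collapses to alpha and the two models share one likelihood
  n <- 1200
  enc <- simulate_responses(n, 3.2, 0.9, 5, delta = 0.1, seed = 14)
  ans <- c(enc$codes, rep(dk_sentinel(), enc$dk_count))
  df <- data.frame(respondent_id = paste0("r", seq_len(n)), country = "XX",
                   location = "rural", sex = "female", age = 40L,
                   politics = "centre", q = ans, stringsAsFactors = FALSE)
  sch <- survey_schema(question_spec("q", 5, dk_label = "DK"))
  ds <- structure(df, schema = sch, class = c("survey_dataset", "data.frame"))
  ctl <- quick_ctl(17, chains = 4, iters = 6000, burn = 2000, thin = 4)
  fit_cov <- suppressWarnings(
    fit_covariate(build_design(ds, "q", "XX"), control = ctl))
  fit_one <- fit_ordinal(enc, control = quick_ctl(18, chains = 4,
                                                  iters = 6000, burn = 2000,
                                                  thin = 4))
  pool_a <- surveyprobit:::pool_draws(fit_cov$draws)[, "alpha"]
  pool_mu <- surveyprobit:::pool_draws(fit_one$draws)[, "mu"]
  ks <- suppressWarnings(ks.test(pool_a, pool_mu))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a simulated male effect is recovered", {
  tr <- covariate_truth(alpha = 3, b_sex = 0.5, sigma = 1)
  q <- question_spec("q", 5)
  scn <- scenario(data.frame(country = "XX", w_rural = 0.5,
                             n_rural = 1000, n_urban = 1000),
                  questions = list(q = list(spec = q, truth = tr)), seed = 23)
  ds <- simulate_survey(scn)
  fit <- fit_covariate(build_design(ds, "q", "XX"),
                       control = quick_ctl(29, chains = 4, iters = 3000,
                                           burn = 1500))
  s <- as.data.frame(summary(fit))
  b2 <- s[s$parameter == "b_sex_male", ]
  expect_lt(abs(b2$mean - 0.5), 3 * b2$sd)
  expect_true(b2$ci_excludes_zero)
})

test_that("shifting all ages leaves the per-sd age effect unchanged", {
  tr <- covariate_truth(alpha = 3, b_age = -0.3, sigma = 1)
  q <- question_spec("q", 5)
  scn <- scenario(data.frame(country = "XX", w_rural = 0.5,
                             n_rural = 600, n_urban = 600),
                  questions = list(q = list(spec = q, truth = tr)), seed = 37)
  ds <- simulate_survey(scn)
  ctl <- quick_ctl(41, chains = 4, iters = 2500, burn = 1000)
  fit1 <- fit_covariate(build_design(ds, "q", "XX"), control = ctl)
  ds2 <- ds
  ds2$age <- ds$age + 7L
  fit2 <- fit_covariate(build_design(ds2, "q", "XX"), control = ctl)
  s1 <- as.data.frame(summary(fit1))
  s2 <- as.data.frame(summary(fit2))
  b1 <- s1[s1$parameter == "b_age_std", ]
  b2 <- s2[s2$parameter == "b_age_std", ]
  expect_lt(abs(b1$mean - b2$mean), 3 * sqrt(b1$sd^2 + b2$sd^2) / 5)
  expect_equal(fit2$design$age_center, fit1$design$age_center + 7)
  expect_equal(fit2$design$age_scale, fit1$design$age_scale)
})

test_that("the coefficient report carries both age scalings and all parameters", {
  d <- design_fixture()
  fit <- suppressWarnings(
    fit_covariate(d, control = quick_ctl(3, chains = 2, iters = 400,
                                         burn = 200)))
  rep <- coefficient_report(fit)
  expect_equal(nrow(rep), length(fit$draws$param_names))
  expect_equal(attr(rep, "age_sd"), d$age_scale)
  v <- rep$mean[rep$parameter == "b_age_std"]
  expect_equal(rep$per_year[rep$parameter == "b_age_std"], v / d$age_scale)
  expect_true(all(c("mean", "sd", "q2.5", "q97.5", "ci_excludes_zero",
                    "rhat") %in% names(rep)))
})
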