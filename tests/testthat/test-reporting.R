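# Batch reporting: exported tables, manifests, determinism, display rounding.

small_panel <- function(seed = 19) {
  q <- question_spec("q", 5, dk_label = "DK")
  truths <- list(
    AA = group_truth(2.7, 3.2, delta_R = 0.15, delta_U = 0.1),
    BB = group_truth(3.4, 3.3, sigma_U = 1.2, delta_R = 0.2, delta_U = 0.2))
  scn <- scenario(data.frame(country = c("AA", "BB"), w_rural = c(0.3, 1),
                             n_rural = 150, n_urban = 150),
                  questions = list(q = list(spec = q, truth = truths)),
                  seed = seed)
  list(survey = simulate_survey(scn), meta = scenario_country_meta(scn))
}

test_that("the group-model run writes valid, reproducible artifacts", {
  panel <- small_panel()
  out1 <- file.path(withr::local_tempdir(), "run1")
  ctl <- quick_ctl(7, chains = 2, iters = 1200, burn = 500)
  res <- run_fit_group(panel$survey, panel$meta, question_id = "q",
                       control = ctl, out_dir = out1)
  expect_equal(res$status, 0L)
  probs <- read.csv(res$paths[["category_probs"]])
  # three levels per country, six categories (DK + 5) each
  expect_equal(nrow(probs), 2 * 3 * 6)
  expect_true(all(c("rural", "urban", "country") %in% probs$level))
  sums <- tapply(probs$mean, list(probs$country, probs$level), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(probs$lower <= probs$mean + 1e-12 &
                    probs$mean <= probs$upper + 1e-12))
  # country BB is entirely rural in the metadata: weighted = rural exactly
  bb <- probs[probs$country == "BB", ]
  expect_equal(bb$mean[bb$level == "country"], bb$mean[bb$level == "rural"],
               tolerance = 1e-12)
  # manifest records the provenance
  man <- jsonlite::read_json(res$paths[["manifest"]])
  expect_equal(man$command, "fit-group")
  expect_equal(man$seed, 7)
  expect_match(man$config_hash, "^[0-9a-f]{8}$")
  # a rerun with the same configuration is byte-identical
  out2 <- file.path(withr::local_tempdir(), "run2")
  res2 <- run_fit_group(panel$survey, panel$meta, question_id = "q",
                        control = ctl, out_dir = out2)
  for (f in c("category_probs", "group_params", "group_contrasts", "rhat")) {
    expect_identical(readLines(res$paths[[f]]), readLines(res2$paths[[f]]))
  }
})

test_that("countries absent from the metadata stop the run before sampling", {
  panel <- small_panel()
  meta <- panel$meta[panel$meta$country != "BB", ]
  t0 <- Sys.time()
  expect_error(run_fit_group(panel$survey, meta, question_id = "q",
                             out_dir = withr::local_tempdir()),
               "absent from the metadata table: BB")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
})

test_that("the covariate run exports a stable coefficient table", {
  panel <- small_panel(seed = 23)
  out <- file.path(withr::local_tempdir(), "cov")
  res <- run_fit_covariate(panel$survey, question_id = "q",
                           control = quick_ctl(3, chains = 2, iters = 1000,
                                               burn = 400),
                           out_dir = out)
  tab <- read.csv(res$paths[["coefficients"]])
  expect_true(all(c("parameter", "mean", "sd", "q2.5", "q97.5",
                    "ci_excludes_zero", "rhat", "per_year", "age_sd",
                    "country", "question_id") %in% names(tab)))
  expect_equal(sort(unique(tab$country)), c("AA", "BB"))
  # one row per sampled parameter per country
  expect_equal(sum(tab$country == "AA"), 12)
})

test_that("recovery runs are config-driven, reproducible and summarized", {
  cfg_path <- file.path(withr::local_tempdir(), "recovery.yaml")
  writeLines(c(
    "model: single",
    "K: 5",
    "sample_size: 400",
    "n_replicates: 2",
    "truth:",
    "  mu: 3.3",
    "  sigma: 1.0",
    "  delta: 0.15",
    "mcmc:",
    "  n_chains: 2",
    "  n_iterations: 800",
    "  burn_in: 300"), cfg_path)
  cfg <- read_recovery_config(cfg_path)
  expect_equal(cfg$n, 400)
  expect_equal(cfg$n_replicates, 2)
  expect_equal(cfg$control$n_chains, 2)
  expect_s3_class(cfg$truth, "single_truth")
  # a config without the sample size is refused outright
  no_n <- sub("sample_size: 400", "n_replicates: 2", readLines(cfg_path))
  bad_path <- file.path(dirname(cfg_path), "bad.yaml")
  writeLines(unique(no_n), bad_path)
  expect_error(read_recovery_config(bad_path), "sample_size")
  out <- file.path(withr::local_tempdir(), "rec")
  res <- run_recover(cfg_path, out_dir = out, seed = 5)
  tab <- read.csv(res$paths[["recovery"]])
  expect_true(all(c("parameter", "truth", "bias", "rmse", "coverage") %in%
                    names(tab)))
  expect_true(all(is.na(tab$coverage) |
                    (tab$coverage >= 0 & tab$coverage <= 1)))
  res2 <- run_recover(cfg_path, out_dir = file.path(out, "again"), seed = 5)
  expect_identical(readLines(res$paths[["recovery"]]),
                   readLines(res2$paths[["recovery"]]))
})

test_that("display percentages round half up at whole-percent granularity", {
  expect_identical(percent_half_up(c(0.365, 0.594, 0.02, 0.125)),
                   c(37L, 59L, 2L, 13L))
  fit <- local({
    set.seed(1)
    r <- simulate_responses(400, 3, 1, 5, delta = 0.3, seed = 2)
    u <- simulate_responses(400, 3.2, 1, 5, delta = 0.3, seed = 3)
    fit_group(r, u, control = quick_ctl(2, chains = 2, iters = 800,
                                        burn = 300))
  })
  shares <- headline_shares(fit, w_rural = 0.25)
  expect_equal(sum(shares) >= 98 && sum(shares) <= 102, TRUE)
  expect_named(shares, c("DK", paste0("cat", 1:5)))
})
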