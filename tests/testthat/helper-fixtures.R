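# Shared fixtures: short MCMC configurations and a tiny canonical survey.

quick_ctl <- function(seed = 1L, chains = 4L, iters = 3000L,
                      burn = 1000L, thin = 1L) {
  mcmc_control(n_chains = chains, n_iterations = iters, burn_in = burn,
               thin = thin, seed = seed)
}

tiny_schema <- function() {
  survey_schema(
    question_spec("q_support", 5,
                  labels = c("strongly_oppose", "oppose", "neutral",
                             "support", "strongly_support"),
                  dk_label = "dont_know"),
    question_spec("q_trend", 5))
}

# Three-respondent canonical survey file; returns its path.
write_tiny_survey <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              rows = NULL) {
  if (is.null(rows)) {
    rows <- c(
      "r1,ES,rural,female,44,centre,2,3",
      "r2,ES,urban,male,31,left,DK,5",
      "r3,SK,rural,male,60,right,5,")
  }
  path <- file.path(dir, "survey.csv")
  writeLines(c("respondent_id,country,location,sex,age,politics,q_support,q_trend",
               rows), path)
  path
}

expect_valid_probs <- function(p, tol = 1e-12) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = tol)
}
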