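# Synthetic surveys with exactly the statistical structure the models assume:
# a normal latent opinion cut at ordered thresholds, an additive DK
# probability, rural/urban differences in latent mean and sd, and covariate
# effects on the latent mean. One random stream per scenario seed with a
# fixed draw order (demographics, then DK indicators, then latent values), so
# datasets are bit-reproducible.

#' Simulate ordinal answers from known latent parameters
#'
#' Each respondent answers "I don't know" with probability `delta`; otherwise
#' a latent value `z ~ normal(mu, sigma)` is drawn and the answer is the
#' category k whose bin `(theta[k-1], theta[k]]` contains z.
#'
#' @param n Number of respondents (>= 0).
#' @param mu,sigma Latent mean and standard deviation.
#' @param K Number of ordinal categories.
#' @param theta_free Free interior thresholds (default: centred at j + 0.5).
#' @param delta DK probability.
#' @param seed Optional seed; when `NULL` the current RNG stream is used (so
#'   the survey-level generator controls one stream).
#' @param has_dont_know Whether the simulated question offers a DK option
#'   (default: yes whenever `delta > 0`).
#' @return An `encoded_responses` object.
#' @export
simulate_responses <- function(n, mu, sigma, K = 5L,
                               theta_free = default_theta_free(K),
                               delta = 0, seed = NULL,
                               has_dont_know = delta > 0) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 0L, delta >= 0, delta <= 1)
  theta <- make_thresholds(K, theta_free)
  if (n == 0L) {
    return(new_encoded(integer(0), 0L, 0L, K, has_dont_know,
                       question_id = "sim"))
  }
  dk <- stats::runif(n) < delta
  z <- stats::rnorm(sum(!dk), mu, sigma)
  codes <- findInterval(z, theta) + 1L
  new_encoded(codes, sum(dk), 0L, K, has_dont_know, question_id = "sim")
}

default_theta_free <- function(K) {
  if (K > 3L) seq(2L, check_K(K) - 2L) + 0.5 else numeric(0)
}

#' True parameter sets for scenario questions
#'
#' `group_truth()` describes a rural/urban question (shared thresholds,
#' group-specific mean, sd and DK probability); `covariate_truth()` describes
#' a question generated from the linear-predictor model, with the age effect
#' expressed per standard deviation of the simulated ages.
#'
#' @param mu_R,mu_U,sigma_R,sigma_U Group latent means and sds.
#' @param theta_free Free interior thresholds (default j + 0.5).
#' @param delta_R,delta_U Group DK probabilities.
#' @return A list of class `group_truth` / `covariate_truth`.
#' @export
group_truth <- function(mu_R, mu_U, sigma_R = 1, sigma_U = 1,
                        theta_free = NULL, delta_R = 0, delta_U = 0) {
  structure(list(mu_R = mu_R, mu_U = mu_U, sigma_R = sigma_R,
                 sigma_U = sigma_U, theta_free = theta_free,
                 delta_R = delta_R, delta_U = delta_U),
            class = "group_truth")
}

#' @rdname group_truth
#' @param mu,sigma Single-group latent mean and sd.
#' @export
single_truth <- function(mu, sigma = 1, theta_free = NULL, delta = 0) {
  structure(list(mu = mu, sigma = sigma, theta_free = theta_free,
                 delta = delta), class = "single_truth")
}

#' @rdname group_truth
#' @param alpha Latent intercept (at the reference profile: rural female of
#'   mean age, political centre).
#' @param b_location,b_sex,b_age Effects of urban location, male sex and age
#'   (per sd of age).
#' @param b_politics Length-4 vector: extreme left, left, right, extreme
#'   right (centre reference).
#' @param sigma Common latent sd.
#' @param delta DK probability.
#' @export
covariate_truth <- function(alpha, b_location = 0, b_sex = 0, b_age = 0,
                            b_politics = c(0, 0, 0, 0), sigma = 1,
                            theta_free = NULL, delta = 0) {
  stopifnot(length(b_politics) == 4L)
  structure(list(alpha = alpha, b_location = b_location, b_sex = b_sex,
                 b_age = b_age, b_politics = b_politics, sigma = sigma,
                 theta_free = theta_free, delta = delta),
            class = "covariate_truth")
}

#' Define a synthetic survey scenario
#'
#' A scenario fixes the panel shape (countries, rural/urban sample sizes and
#' rural population weights), the questions with their generating truths, the
#' demographic generators and the seed. The default demographic generators
#' follow a balanced online panel: sex exactly balanced, age from a normal
#' distribution truncated to 18-95 years, political orientation categorical.
#'
#' @param countries Data frame with columns `country`, `w_rural`, `n_rural`,
#'   `n_urban`.
#' @param questions Named list (by question id); each element a list with
#'   `spec` (a [question_spec()]) and `truth` (a [group_truth()] or
#'   [covariate_truth()], or a named list of them keyed by country code).
#' @param age_mean,age_sd Age distribution (years) before truncation to
#'   \[18, 95\].
#' @param politics_probs Named probabilities for extreme_left, left, centre,
#'   right, extreme_right.
#' @param seed Scenario seed.
#' @return Object of class `scenario`.
#' @export
scenario <- function(countries, questions, age_mean = 49, age_sd = 17,
                     politics_probs = c(extreme_left = 0.08, left = 0.24,
                                        centre = 0.36, right = 0.24,
                                        extreme_right = 0.08),
                     seed = 1L) {
  stopifnot(all(c("country", "w_rural", "n_rural", "n_urban") %in%
                  names(countries)),
            all(countries$n_rural >= 0), all(countries$n_urban >= 0),
            all(countries$w_rural >= 0 & countries$w_rural <= 1),
            abs(sum(politics_probs) - 1) < 1e-8,
            length(politics_probs) == 5L)
  for (qid in names(questions)) {
    q <- questions[[qid]]
    stopifnot(inherits(q$spec, "question_spec"))
    if (!inherits(q$truth, c("group_truth", "covariate_truth"))) {
      stopifnot(is.list(q$truth),
                all(countries$country %in% names(q$truth)))
    }
  }
  structure(list(countries = countries, questions = questions,
                 age_mean = age_mean, age_sd = age_sd,
                 politics_probs = politics_probs, seed = as.integer(seed)),
            class = "scenario")
}

country_truth <- function(q, code) {
  if (inherits(q$truth, c("group_truth", "covariate_truth"))) q$truth
  else q$truth[[code]]
}

# Truncated-normal ages via inverse-CDF so the draw count is fixed.
draw_ages <- function(n, mean, sd, lo = 18, hi = 95) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(as.integer(round(stats::qnorm(u, mean, sd))), lo), hi)
}

#' Simulate a full respondent-level survey from a scenario
#'
#' Demographics are drawn first (ages, exactly balanced sexes, political
#' orientation), then for each question the DK indicators, then the latent
#' values. Group-truth questions use the respondent's rural/urban group
#' parameters; covariate-truth questions compute each respondent's latent
#' mean from the linear predictor (age entering per empirical sd within the
#' country stratum, matching how the model standardizes age).
#'
#' @param scn A [scenario()].
#' @return A `survey_dataset` that round-trips through [write_survey()] /
#'   [read_survey()].
#' @export
simulate_survey <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  pol_levels <- c("extreme_left", "left", "centre", "right", "extreme_right")
  rows <- list()
  for (ci in seq_len(nrow(scn$countries))) {
    code <- scn$countries$country[ci]
    for (grp in c("rural", "urban")) {
      n <- scn$countries[[if (grp == "rural") "n_rural" else "n_urban"]][ci]
      if (n == 0L) next
      age <- draw_ages(n, scn$age_mean, scn$age_sd)
      n_male <- n %/% 2L
      sex <- c(rep("female", n - n_male), rep("male", n_male))
      politics <- pol_levels[sample.int(5L, n, replace = TRUE,
                                        prob = scn$politics_probs)]
      rows[[length(rows) + 1L]] <- data.frame(
        respondent_id = sprintf("%s_%s_%05d", code, substr(grp, 1L, 1L),
                                seq_len(n)),
        country = code, location = grp, sex = sex, age = age,
        politics = politics, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  for (qid in names(scn$questions)) {
    q <- scn$questions[[qid]]
    K <- q$spec$K
    ans <- rep(NA_integer_, nrow(df))
    for (code in scn$countries$country) {
      tr <- country_truth(q, code)
      in_country <- df$country == code
      if (!any(in_country)) next
      if (inherits(tr, "group_truth")) {
        th_free <- if (is.null(tr$theta_free)) default_theta_free(K) else tr$theta_free
        theta <- make_thresholds(K, th_free)
        for (grp in c("rural", "urban")) {
          idx <- which(in_country & df$location == grp)
          if (!length(idx)) next
          mu <- if (grp == "rural") tr$mu_R else tr$mu_U
          sig <- if (grp == "rural") tr$sigma_R else tr$sigma_U
          del <- if (grp == "rural") tr$delta_R else tr$delta_U
          dk <- stats::runif(length(idx)) < del
          z <- stats::rnorm(sum(!dk), mu, sig)
          ans[idx[dk]] <- dk_sentinel()
          ans[idx[!dk]] <- findInterval(z, theta) + 1L
        }
      } else {
        idx <- which(in_country)
        th_free <- if (is.null(tr$theta_free)) default_theta_free(K) else tr$theta_free
        theta <- make_thresholds(K, th_free)
        age_i <- df$age[idx]
        age_std <- (age_i - mean(age_i)) / stats::sd(age_i)
        mu_i <- tr$alpha +
          tr$b_location * (df$location[idx] == "urban") +
          tr$b_sex * (df$sex[idx] == "male") +
          tr$b_age * age_std +
          tr$b_politics[1L] * (df$politics[idx] == "extreme_left") +
          tr$b_politics[2L] * (df$politics[idx] == "left") +
          tr$b_politics[3L] * (df$politics[idx] == "right") +
          tr$b_politics[4L] * (df$politics[idx] == "extreme_right")
        dk <- stats::runif(length(idx)) < tr$delta
        z <- stats::rnorm(sum(!dk), mu_i[!dk], tr$sigma)
        ans[idx[dk]] <- dk_sentinel()
        ans[idx[!dk]] <- findInterval(z, theta) + 1L
      }
    }
    df[[qid]] <- ans
  }
  schema <- survey_schema(lapply(scn$questions, `[[`, "spec"))
  structure(df, schema = schema, class = c("survey_dataset", "data.frame"))
}

#' A default scenario mirroring a balanced multi-country panel
#'
#' 23 countries with roughly 500 respondents each, split equally between
#' rural and urban strata, one five-category attitude question with a DK
#' option. Group truths vary smoothly across countries around a mildly
#' supportive mean with a small rural/urban gap and DK shares between about
#' 0.1 and 0.3. Rural weights are illustrative round figures; real analyses
#' supply their own country metadata.
#'
#' @param n_per_country Respondents per country (split half rural/urban).
#' @param seed Scenario seed.
#' @return A [scenario()].
#' @export
default_scenario <- function(n_per_country = 500L, seed = 1L) {
  codes <- c("AT", "BE", "BG", "CZ", "DE", "DK", "EE", "ES", "FI", "FR",
             "GR", "HR", "HU", "IT", "LT", "LV", "NL", "PL", "PT", "RO",
             "SE", "SI", "SK")
  w <- c(0.41, 0.02, 0.24, 0.26, 0.22, 0.12, 0.30, 0.19, 0.14, 0.18,
         0.19, 0.42, 0.27, 0.28, 0.31, 0.31, 0.07, 0.40, 0.32, 0.46,
         0.11, 0.44, 0.46)
  i <- seq_along(codes)
  n_r <- n_per_country %/% 2L
  countries <- data.frame(country = codes, w_rural = w,
                          n_rural = n_r, n_urban = n_per_country - n_r)
  truths <- lapply(i, function(j) {
    group_truth(mu_R = 3 + 0.5 * sin(j), mu_U = 3 + 0.5 * sin(j) + 0.1,
                sigma_R = 1, sigma_U = 1.1,
                delta_R = 0.2 + 0.1 * cos(j), delta_U = 0.18 + 0.1 * cos(j))
  })
  names(truths) <- codes
  q <- question_spec("recovery_support", 5,
                     labels = c("strongly_oppose", "oppose", "neutral",
                                "support", "strongly_support"),
                     dk_label = "dont_know")
  scenario(countries,
           questions = list(recovery_support = list(spec = q, truth = truths)),
           seed = seed)
}

#' Country metadata matching a scenario
#'
#' @param scn A [scenario()].
#' @return A `country_meta` data frame with the scenario's rural weights.
#' @export
scenario_country_meta <- function(scn) {
  structure(data.frame(country = scn$countries$country,
                       rural_proportion = scn$countries$w_rural,
                       median_age = NA_real_, stringsAsFactors = FALSE),
            class = c("country_meta", "data.frame"))
}

truth_vector <- function(truth, K, model) {
  th <- if (is.null(truth$theta_free)) default_theta_free(K) else truth$theta_free
  switch(model,
    single = {
      has_dk <- truth$delta > 0
      stats::setNames(c(truth$mu, truth$sigma, th,
                        if (has_dk) truth$delta),
                      param_names_single(K, has_dk))
    },
    group = {
      has_dk <- truth$delta_R > 0 || truth$delta_U > 0
      stats::setNames(c(truth$mu_R, truth$mu_U, truth$sigma_R, truth$sigma_U,
                        th, if (has_dk) c(truth$delta_R, truth$delta_U)),
                      param_names_group(K, has_dk))
    },
    covariate = {
      has_dk <- truth$delta > 0
      stats::setNames(
        c(truth$alpha, truth$b_location, truth$b_sex, truth$b_age,
          truth$b_politics, truth$sigma, th, if (has_dk) truth$delta),
        c(COEF_NAMES, "sigma",
          if (K > 3L) paste0("theta", seq(2L, K - 2L)),
          if (has_dk) "delta"))
    })
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates data from known parameters, fits the corresponding
#' model and records, per parameter, the posterior mean error, posterior sd,
#' whether the central 95% credible interval covers the truth, and R-hat.
#' Replicates where any parameter has R-hat above `rhat_threshold` are
#' flagged as non-converged and excluded from the coverage summary (the
#' count is reported).
#'
#' @param truth A `single`-model truth list (`mu`, `sigma`, optional
#'   `theta_free`, `delta`), a [group_truth()] or a [covariate_truth()].
#' @param n Respondents per replicate (per group for the group model).
#' @param K Number of ordinal categories.
#' @param n_replicates Number of simulate-fit replicates.
#' @param control An [mcmc_control()]; its seed is re-derived per replicate.
#' @param seed Experiment seed.
#' @param priors Optional [prior_spec()].
#' @param rhat_threshold Convergence flag threshold.
#' @return Object of class `recovery_report`: a data frame with one row per
#'   free parameter (truth, bias, rmse, mean posterior sd, empirical
#'   coverage, replicates used) plus attributes `n_nonconverged` and
#'   `n_replicates`.
#' @export
recovery_experiment <- function(truth, n, K = 5L, n_replicates = 20L,
                                control = mcmc_control(), seed = 1L,
                                priors = NULL, rhat_threshold = 1.1) {
  model <- if (inherits(truth, "group_truth")) "group"
  else if (inherits(truth, "covariate_truth")) "covariate"
  else "single"
  tv <- truth_vector(truth, K, model)
  p <- length(tv)
  est <- sds <- matrix(NA_real_, n_replicates, p,
                       dimnames = list(NULL, names(tv)))
  cover <- matrix(NA, n_replicates, p)
  converged <- logical(n_replicates)

  for (r in seq_len(n_replicates)) {
    sim_seed <- seed + 1000L * r
    ctl <- control
    ctl$seed <- seed + 1000L * r + 500L
    fit <- switch(model,
      single = {
        enc <- simulate_responses(n, truth$mu, truth$sigma, K,
                                  theta_free = if (is.null(truth$theta_free))
                                    default_theta_free(K) else truth$theta_free,
                                  delta = truth$delta, seed = sim_seed)
        fit_ordinal(enc, priors, ctl)
      },
      group = {
        set.seed(sim_seed)
        th <- if (is.null(truth$theta_free)) default_theta_free(K) else truth$theta_free
        rur <- simulate_responses(n, truth$mu_R, truth$sigma_R, K, th,
                                  truth$delta_R,
                                  has_dont_know = truth$delta_R > 0 ||
                                    truth$delta_U > 0)
        urb <- simulate_responses(n, truth$mu_U, truth$sigma_U, K, th,
                                  truth$delta_U,
                                  has_dont_know = truth$delta_R > 0 ||
                                    truth$delta_U > 0)
        fit_group(rur, urb, priors, ctl)
      },
      covariate = {
        q <- question_spec("q", K, dk_label = if (truth$delta > 0) "DK")
        scn <- scenario(
          data.frame(country = "XX", w_rural = 0.5,
                     n_rural = n %/% 2L, n_urban = n - n %/% 2L),
          questions = list(q = list(spec = q, truth = truth)),
          seed = sim_seed)
        ds <- simulate_survey(scn)
        fit_covariate(build_design(ds, "q", "XX"), priors = priors,
                      control = ctl)
      })
    s <- as.data.frame(summary(fit))
    s <- s[match(names(tv), s$parameter), ]
    est[r, ] <- s$mean
    sds[r, ] <- s$sd
    cover[r, ] <- s$q2.5 <= tv & tv <= s$q97.5
    converged[r] <- all(is.na(s$rhat) | s$rhat <= rhat_threshold)
  }

  err <- sweep(est, 2L, tv)
  used <- converged
  out <- data.frame(
    parameter = names(tv), truth = unname(tv),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2)),
    mean_post_sd = colMeans(sds),
    coverage = if (any(used)) colMeans(cover[used, , drop = FALSE]) else NA_real_,
    n_used = sum(used), row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_nonconverged") <- sum(!converged)
  attr(out, "n_replicates") <- n_replicates
  attr(out, "model") <- model
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Parameter recovery (", attr(x, "model"), " model, ",
      attr(x, "n_replicates"), " replicates, ",
      attr(x, "n_nonconverged"), " non-converged excluded from coverage)\n",
      sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
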