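# Numbers-first reporting: every artifact is a delimiter-separated table plus
# a JSON run manifest (seed, configuration hash, package version), so a run
# is reproducible byte for byte from the manifest alone.

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, for config
# fingerprints; exact in double arithmetic since h * 31 + b < 2^53.
string_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  string_hash(paste(deparse(cfg, control = "all"), collapse = ""))
}

write_manifest <- function(path, command, seed, cfg, extra = list()) {
  manifest <- c(list(command = command,
                     package = "surveyprobit",
                     version = as.character(utils::packageVersion("surveyprobit")),
                     seed = seed,
                     config_hash = config_hash(cfg)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Round a proportion to a display percentage (half up)
#'
#' Display granularity for headline shares is whole percentages, rounded
#' half up (0.365 -> 37); full precision is retained in the exported tables.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Integer percentage(s).
#' @export
percent_half_up <- function(p) {
  as.integer(floor(p * 100 + 0.5))
}

as_survey <- function(x, schema, sep = ",") {
  if (inherits(x, "survey_dataset")) x else read_survey(x, schema, sep = sep)
}

as_meta <- function(x, sep = ",") {
  if (inherits(x, "country_meta")) x else read_country_meta(x, sep = sep)
}

as_schema <- function(x) {
  if (inherits(x, "survey_schema")) x else read_schema(x)
}

#' Fit the group model across countries and export its summary tables
#'
#' For each requested country: encodes the rural and urban strata, fits the
#' shared-threshold group model, and accumulates (i) rural, urban and
#' population-weighted country-level posterior category probabilities,
#' (ii) parameter summaries, (iii) rural/urban contrasts and (iv) R-hat
#' values. Tables are written to `out_dir` together with a JSON manifest.
#' Countries missing from the metadata table are reported before any
#' sampling starts.
#'
#' @param survey A `survey_dataset` or path to a canonical survey file.
#' @param country_meta A `country_meta` or path to the metadata file.
#' @param schema A `survey_schema` or path to a schema YAML (ignored when
#'   `survey` is already a dataset).
#' @param question_id Question to fit.
#' @param countries Country codes to fit (default: all in the survey).
#' @param control An [mcmc_control()].
#' @param priors Optional [prior_spec()].
#' @param out_dir Output directory (created if needed).
#' @param rhat_threshold Convergence threshold; any parameter above it makes
#'   the returned status nonzero.
#' @return Invisibly, a list with `status` (0 on convergence), `paths` of the
#'   written artifacts and the per-country fits.
#' @export
run_fit_group <- function(survey, country_meta, schema = NULL, question_id,
                          countries = NULL, control = mcmc_control(),
                          priors = NULL, out_dir = ".",
                          rhat_threshold = 1.1) {
  if (!is.null(schema)) schema <- as_schema(schema)
  survey <- as_survey(survey, schema)
  meta <- as_meta(country_meta)
  if (is.null(countries)) countries <- sort(unique(survey$country))
  missing_meta <- setdiff(countries, meta$country)
  if (length(missing_meta)) {
    stop("countries absent from the metadata table: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  probs_tbl <- params_tbl <- contr_tbl <- rhat_tbl <- list()
  fits <- list()
  for (code in countries) {
    rur <- encode_responses(survey, question_id, code, "rural")
    urb <- encode_responses(survey, question_id, code, "urban")
    fit <- fit_group(rur, urb, priors, control)
    fits[[code]] <- fit
    w <- meta$rural_proportion[meta$country == code]
    for (cp in list(posterior_category_probs(fit, "rural"),
                    posterior_category_probs(fit, "urban"),
                    country_posterior(fit, w))) {
      probs_tbl[[length(probs_tbl) + 1L]] <- as.data.frame(cp)
    }
    s <- as.data.frame(summary(fit))
    s$country <- code
    params_tbl[[code]] <- s
    ct <- as.data.frame(group_contrast(fit))
    ct$country <- code
    contr_tbl[[code]] <- ct
    rhat_tbl[[code]] <- data.frame(country = code, parameter = s$parameter,
                                   rhat = s$rhat)
  }
  paths <- c(category_probs = file.path(out_dir, "category_probs.csv"),
             group_params = file.path(out_dir, "group_params.csv"),
             group_contrasts = file.path(out_dir, "group_contrasts.csv"),
             rhat = file.path(out_dir, "rhat.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(do.call(rbind, probs_tbl), paths["category_probs"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, params_tbl), paths["group_params"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, contr_tbl), paths["group_contrasts"],
                   row.names = FALSE, quote = FALSE)
  rhat_all <- do.call(rbind, rhat_tbl)
  utils::write.csv(rhat_all, paths["rhat"], row.names = FALSE, quote = FALSE)
  cfg <- list(question_id = question_id, countries = countries,
              control = unclass(control), rhat_threshold = rhat_threshold)
  write_manifest(paths["manifest"], "fit-group", control$seed, cfg,
                 list(question_id = question_id, countries = countries,
                      rhat_threshold = rhat_threshold))
  status <- as.integer(any(!is.na(rhat_all$rhat) &
                             rhat_all$rhat > rhat_threshold))
  invisible(list(status = status, paths = paths, fits = fits))
}

#' Fit the covariate model across countries and export coefficient tables
#'
#' Analogue of [run_fit_group()] for the linear-predictor model: one
#' coefficient-report row per parameter per country, written to
#' `coefficients.csv` with a JSON manifest.
#'
#' @inheritParams run_fit_group
#' @return Invisibly, a list with `status`, `paths` and the fits.
#' @export
run_fit_covariate <- function(survey, schema = NULL, question_id,
                              countries = NULL, control = mcmc_control(),
                              priors = NULL, out_dir = ".",
                              rhat_threshold = 1.1) {
  if (!is.null(schema)) schema <- as_schema(schema)
  survey <- as_survey(survey, schema)
  if (is.null(countries)) countries <- sort(unique(survey$country))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coef_tbl <- list()
  fits <- list()
  for (code in countries) {
    fit <- fit_covariate(build_design(survey, question_id, code),
                         priors = priors, control = control)
    fits[[code]] <- fit
    rep <- as.data.frame(coefficient_report(fit))
    rep$age_sd <- attr(coefficient_report(fit), "age_sd")
    rep$country <- code
    rep$question_id <- question_id
    coef_tbl[[code]] <- rep
  }
  paths <- c(coefficients = file.path(out_dir, "coefficients.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  all_coef <- do.call(rbind, coef_tbl)
  utils::write.csv(all_coef, paths["coefficients"], row.names = FALSE,
                   quote = FALSE)
  cfg <- list(question_id = question_id, countries = countries,
              control = unclass(control), rhat_threshold = rhat_threshold)
  write_manifest(paths["manifest"], "fit-covariate", control$seed, cfg,
                 list(question_id = question_id, countries = countries))
  status <- as.integer(any(!is.na(all_coef$rhat) &
                             all_coef$rhat > rhat_threshold))
  invisible(list(status = status, paths = paths, fits = fits))
}

#' Read a recovery-experiment configuration
#'
#' YAML file with fields `model` (single/group/covariate), `K`,
#' `sample_size` (respondents per replicate, per group for the group model),
#' `n_replicates`, `truth` (named values matching the model's truth
#' constructor) and optionally `mcmc` (overrides for [mcmc_control()]).
#' The key is called `sample_size` deliberately: a bare `n` is a boolean
#' literal in YAML 1.1 and silently disappears as a key.
#'
#' @param path Path to the YAML config.
#' @return List with `truth`, `n`, `K`, `n_replicates`, `control`.
#' @export
read_recovery_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$model), !is.null(cfg$truth))
  if (is.null(cfg$sample_size)) {
    stop("recovery config needs a 'sample_size' field", call. = FALSE)
  }
  tr <- cfg$truth
  truth <- switch(cfg$model,
    single = single_truth(tr$mu, tr$sigma %||% 1,
                          unlist(tr$theta_free), tr$delta %||% 0),
    group = group_truth(tr$mu_R, tr$mu_U, tr$sigma_R %||% 1,
                        tr$sigma_U %||% 1, unlist(tr$theta_free),
                        tr$delta_R %||% 0, tr$delta_U %||% 0),
    covariate = covariate_truth(tr$alpha, tr$b_location %||% 0,
                                tr$b_sex %||% 0, tr$b_age %||% 0,
                                unlist(tr$b_politics) %||% c(0, 0, 0, 0),
                                tr$sigma %||% 1, unlist(tr$theta_free),
                                tr$delta %||% 0),
    stop("unknown model '", cfg$model, "'", call. = FALSE))
  control <- do.call(mcmc_control, cfg$mcmc %||% list())
  list(truth = truth, n = cfg$sample_size, K = cfg$K %||% 5L,
       n_replicates = cfg$n_replicates %||% 20L, control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a recovery experiment and export its report
#'
#' @param config Path to a recovery YAML config (see
#'   [read_recovery_config()]) or an equivalent list.
#' @param out_dir Output directory.
#' @param seed Experiment seed (overrides the config control seed for the
#'   simulation stream).
#' @return Invisibly, a list with `status` (0), `paths` and the
#'   `recovery_report`.
#' @export
run_recover <- function(config, out_dir = ".", seed = 1L) {
  cfg <- if (is.character(config)) read_recovery_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- recovery_experiment(cfg$truth, n = cfg$n, K = cfg$K,
                                n_replicates = cfg$n_replicates,
                                control = cfg$control, seed = seed)
  paths <- c(recovery = file.path(out_dir, "recovery.csv"),
             summary = file.path(out_dir, "recovery_summary.txt"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(as.data.frame(report), paths["recovery"],
                   row.names = FALSE, quote = FALSE)
  con <- file(paths["summary"], "w")
  sink(con); print(report); sink(); close(con)
  write_manifest(paths["manifest"], "recover", seed,
                 list(cfg = cfg[c("n", "K", "n_replicates")],
                      control = unclass(cfg$control)),
                 list(n_nonconverged = attr(report, "n_nonconverged")))
  invisible(list(status = 0L, paths = paths, report = report))
}

#' Headline answer shares for a fitted country
#'
#' Convenience summary in display units: the posterior mean probability of
#' each answer category as a whole percentage (rounded half up), at country
#' level for a group fit.
#'
#' @param fit A `group_fit`.
#' @param w_rural Rural population proportion.
#' @return Named integer vector of percentages.
#' @export
headline_shares <- function(fit, w_rural) {
  cp <- country_posterior(fit, w_rural)
  stats::setNames(percent_half_up(cp$mean), cp$labels)
}
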