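# Linear-predictor model: the latent mean of respondent i is
#   mu_i = alpha + b_location * urban_i + b_sex * male_i + b_age * age_std_i
#          + politics dummies (centre is the reference level),
# while sigma, the thresholds and the DK probability are common to all
# respondents. Age is standardized over the fitted stratum for sampler
# stability; the per-year coefficient is recovered by dividing by the age sd.

COEF_NAMES <- c("alpha", "b_location_urban", "b_sex_male", "b_age_std",
                "b_pol_extreme_left", "b_pol_left", "b_pol_right",
                "b_pol_extreme_right")

#' Build the design matrix for the covariate model
#'
#' Selects a country stratum (all locations), drops respondents with a
#' missing answer or a missing political orientation (listwise deletion,
#' counted and reported), encodes the remaining answers and builds the
#' aligned design matrix: intercept, urban indicator (rural reference), male
#' indicator (female reference), standardized age, and four political dummies
#' (extreme left, left, right, extreme right; centre reference). Rows are
#' aligned to the ordinal observations; DK answers contribute only their
#' count (the DK probability does not depend on covariates).
#'
#' @param dataset A `survey_dataset`.
#' @param question_id Question to model.
#' @param country Two-letter country code, or `NULL` for all countries.
#' @return Object of class `design_data`: list with `encoded`
#'   (`encoded_responses`), `X` (design matrix for the ordinal rows),
#'   `age_center`, `age_scale`, `n_dropped` (respondents removed by listwise
#'   deletion), `question_id`, `country`.
#' @export
build_design <- function(dataset, question_id, country = NULL) {
  schema <- attr(dataset, "schema")
  if (is.null(schema) || !question_id %in% names(schema)) {
    stop("question '", question_id, "' is not in the dataset schema",
         call. = FALSE)
  }
  q <- schema[[question_id]]
  df <- as.data.frame(dataset)
  if (!is.null(country)) df <- df[df$country == country, , drop = FALSE]
  if (!nrow(df)) {
    stop("empty stratum: no respondents for country ",
         if (is.null(country)) "all" else country, call. = FALSE)
  }
  ans <- df[[question_id]]
  keep <- !is.na(ans) & df$politics != "missing"
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ans <- ans[keep]
  if (!nrow(df)) {
    stop("no respondents left after dropping missing answers/covariates",
         call. = FALSE)
  }
  if (all(df$politics == "missing")) {
    stop("political orientation is missing for the whole stratum; ",
         "the model as specified is unidentifiable", call. = FALSE)
  }
  is_dk <- ans == dk_sentinel()
  ord <- df[!is_dk, , drop = FALSE]
  age_center <- mean(ord$age)
  age_scale <- stats::sd(ord$age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  X <- cbind(
    intercept = 1,
    location_urban = as.numeric(ord$location == "urban"),
    sex_male = as.numeric(ord$sex == "male"),
    age_std = (ord$age - age_center) / age_scale,
    pol_extreme_left = as.numeric(ord$politics == "extreme_left"),
    pol_left = as.numeric(ord$politics == "left"),
    pol_right = as.numeric(ord$politics == "right"),
    pol_extreme_right = as.numeric(ord$politics == "extreme_right"))
  enc <- new_encoded(codes = ans[!is_dk], dk_count = sum(is_dk),
                     n_missing = n_dropped, K = q$K,
                     has_dont_know = q$has_dont_know,
                     question_id = question_id,
                     country = if (is.null(country)) "all" else country,
                     category_labels = q$labels, dk_label = q$dk_label)
  structure(list(encoded = enc, X = X, age_center = age_center,
                 age_scale = age_scale, n_dropped = n_dropped,
                 question_id = question_id,
                 country = if (is.null(country)) "all" else country),
            class = "design_data")
}

# Ordered-probit log-likelihood with per-observation latent means.
loglik_linpred <- function(y, mu_i, sigma, theta_full) {
  p <- stats::pnorm((theta_full[y + 1L] - mu_i) / sigma) -
    stats::pnorm((theta_full[y] - mu_i) / sigma)
  p <- pmax(p, 0)
  if (any(p == 0)) return(-Inf)
  sum(log(p))
}

#' Fit the covariate (linear-predictor) latent ordinal model
#'
#' Ordered-probit model in which the latent mean is a linear function of
#' respondent covariates (see [build_design()]); `sigma` is modelled
#' independently of the predictors, thresholds keep their fixed extremes, and
#' DK answers keep a single covariate-free probability. Near-flat normal
#' priors are placed on the intercept (centred at the scale midpoint) and the
#' coefficients (centred at zero).
#'
#' @param design A [build_design()] result, or a `survey_dataset` (in which
#'   case `question_id` and `country` select the stratum).
#' @param question_id,country Used only when `design` is a `survey_dataset`.
#' @param priors A [prior_spec()]; defaults to `prior_spec(K)`.
#' @param control An [mcmc_control()].
#' @return Object of class `covariate_fit`. Constant (unidentifiable)
#'   design columns trigger a warning and are listed in `$unidentifiable`.
#' @export
fit_covariate <- function(design, question_id = NULL, country = NULL,
                          priors = NULL, control = mcmc_control()) {
  if (inherits(design, "survey_dataset")) {
    design <- build_design(design, question_id, country)
  }
  stopifnot(inherits(design, "design_data"))
  enc <- design$encoded
  if (is_empty_stratum(enc)) stop("empty stratum", call. = FALSE)
  if (!length(enc$codes)) {
    stop("no ordinal (non-DK) answers: covariate effects are inestimable",
         call. = FALSE)
  }
  K <- enc$K
  if (is.null(priors)) priors <- prior_spec(K)
  stopifnot(priors$K == K)
  has_dk <- enc$has_dont_know
  n_th <- n_free_thresholds(K)
  X <- design$X
  nb <- ncol(X)

  const_cols <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2,
                                      function(v) length(unique(v)) == 1L)]
  if (length(const_cols)) {
    warning("design column(s) constant in this stratum (coefficient not ",
            "identifiable): ", paste(const_cols, collapse = ", "),
            call. = FALSE)
  }

  nm <- c(COEF_NAMES, "sigma",
          if (n_th) paste0("theta", seq(2L, K - 2L)),
          if (has_dk) "delta")
  y <- enc$codes
  n_ord <- length(y)
  dk_count <- enc$dk_count

  log_post <- function(par) {
    beta <- par[seq_len(nb)]
    sigma <- par[nb + 1L]
    th_free <- if (n_th) par[nb + 1L + seq_len(n_th)] else numeric(0)
    delta <- if (has_dk) par[length(par)] else NULL
    lp <- dunif_log(sigma, priors$sigma_lower, priors$sigma_upper)
    if (!is.finite(lp)) return(-Inf)
    theta <- make_thresholds(K, th_free)
    if (is.unsorted(theta, strictly = TRUE)) return(-Inf)
    if (has_dk) {
      ld <- dunif_log(delta, priors$delta_lower, priors$delta_upper)
      if (!is.finite(ld)) return(-Inf)
      lp <- lp + ld
    }
    lp <- lp +
      stats::dnorm(beta[1L], priors$mu_mean, priors$beta_sd, log = TRUE) +
      sum(stats::dnorm(beta[-1L], 0, priors$beta_sd, log = TRUE))
    if (n_th) {
      lp <- lp + sum(stats::dnorm(th_free, seq(2L, K - 2L) + 0.5,
                                  priors$theta_sd, log = TRUE))
    }
    mu_i <- drop(X %*% beta)
    ll <- loglik_linpred(y, mu_i, sigma, c(-Inf, theta, Inf))
    if (has_dk) ll <- ll + dk_loglik(dk_count, n_ord, delta)
    lp + ll
  }

  sd0 <- min(max(stats::sd(y), 0.3), 3 * K)
  center <- c(mean(y), rep(0, nb - 1L), sd0,
              if (n_th) seq(2L, K - 2L) + 0.5,
              if (has_dk) (dk_count + 1) / (enc$n_total + 2))
  init <- make_inits(center, control, priors,
                     delta_idx = if (has_dk) length(nm) else integer(0),
                     sigma_idx = nb + 1L)
  blocks <- c(list(seq_len(nb)),
              as.list(nb + seq_len(length(nm) - nb)))
  draws <- sample_posterior(log_post, init, control, param_names = nm,
                            blocks = blocks)
  out <- list(draws = draws, summary = summarize_draws(draws),
              design = design, priors = priors, control = control,
              K = K, has_dont_know = has_dk,
              unidentifiable = const_cols, call = match.call())
  class(out) <- "covariate_fit"
  out
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("Latent ordinal model with linear predictors\n")
  cat("  question '", x$design$question_id, "', country ", x$design$country,
      "; n = ", x$design$encoded$n_total, " (", x$design$encoded$dk_count,
      " DK), K = ", x$K, "; ", x$design$n_dropped,
      " respondents dropped (missing answer or covariate)\n\n", sep = "")
  print(coefficient_report(x))
  if (length(x$unidentifiable)) {
    cat("\n  unidentifiable (constant in stratum):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.covariate_fit <- function(object, ...) object$summary

#' @export
coef.covariate_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Coefficient table for a covariate-model fit
#'
#' One row per sampled parameter with posterior mean, sd, 95% credible
#' interval, the interval-excludes-zero flag and R-hat. The age effect is
#' estimated per standard deviation of age in the fitted stratum; the
#' `per_year` column divides it by that sd (stored as attribute `age_sd`) so
#' both scalings are available.
#'
#' @param fit A [fit_covariate()] result.
#' @return Data frame of class `coef_report`.
#' @export
coefficient_report <- function(fit) {
  stopifnot(inherits(fit, "covariate_fit"))
  s <- as.data.frame(fit$summary)
  s$per_year <- ifelse(s$parameter == "b_age_std",
                       s$mean / fit$design$age_scale, NA_real_)
  attr(s, "age_sd") <- fit$design$age_scale
  class(s) <- c("coef_report", "data.frame")
  s
}

#' @export
print.coef_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print.data.frame(y, row.names = FALSE)
  cat("  (age coefficient is per sd of age; age sd =",
      signif(attr(x, "age_sd"), 4), "years)\n")
  invisible(x)
}

#' @export
predict.covariate_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stop("supply newdata: a data.frame with columns location, sex, age, ",
         "politics", call. = FALSE)
  }
  d <- object$design
  X <- cbind(1, as.numeric(newdata$location == "urban"),
             as.numeric(newdata$sex == "male"),
             (newdata$age - d$age_center) / d$age_scale,
             as.numeric(newdata$politics == "extreme_left"),
             as.numeric(newdata$politics == "left"),
             as.numeric(newdata$politics == "right"),
             as.numeric(newdata$politics == "extreme_right"))
  pool <- pool_draws(object$draws)
  K <- object$K
  n_th <- n_free_thresholds(K)
  out <- vector("list", nrow(X))
  for (r in seq_len(nrow(X))) {
    mu <- drop(pool[, seq_len(ncol(X))] %*% X[r, ])
    probs <- matrix(NA_real_, nrow(pool), K + object$has_dont_know)
    for (i in seq_len(nrow(pool))) {
      th_free <- if (n_th) pool[i, ncol(X) + 1L + seq_len(n_th)] else numeric(0)
      p <- category_probs(mu[i], pool[i, "sigma"], make_thresholds(K, th_free))
      out_p <- if (object$has_dont_know) dk_adjust(p, pool[i, "delta"]) else p
      probs[i, ] <- out_p
    }
    out[[r]] <- new_category_probs(probs, K, object$has_dont_know,
                                   level = "profile",
                                   question_id = d$question_id,
                                   country = d$country)
  }
  if (length(out) == 1L) out[[1L]] else out
}
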