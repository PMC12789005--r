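# Parameter vector layout for the two-group model:
# (mu_R, mu_U, sigma_R, sigma_U, theta2..theta[K-2], delta_R?, delta_U?).
# Thresholds are shared across groups; they define the response categories,
# which are identical for rural and urban respondents.

param_names_group <- function(K, has_dk) {
  c("mu_R", "mu_U", "sigma_R", "sigma_U",
    if (K > 3L) paste0("theta", seq(2L, K - 2L)),
    if (has_dk) c("delta_R", "delta_U"))
}

#' Fit the rural/urban group model with shared thresholds
#'
#' Joint Bayesian fit of the latent ordinal model for two strata: each group
#' g in \{R, U\} has its own latent mean `mu_g` and standard deviation
#' `sigma_g` (and DK probability `delta_g` where applicable) while the
#' threshold vector is shared, since the response categories mean the same
#' thing in both groups. Priors are independent across groups, reflecting no
#' prior assumption about rural/urban differences. This is the model behind
#' country-level estimates for balanced rural/urban panels: fit both groups,
#' then reweight with [country_posterior()].
#'
#' @param rural,urban [encode_responses()] objects for the two strata; both
#'   must be non-empty and share `K` and the DK flag.
#' @param priors A [prior_spec()]; defaults to `prior_spec(K)`.
#' @param control An [mcmc_control()].
#' @return Object of class `group_fit`.
#' @export
fit_group <- function(rural, urban, priors = NULL, control = mcmc_control()) {
  stopifnot(inherits(rural, "encoded_responses"),
            inherits(urban, "encoded_responses"))
  for (e in list(rural, urban)) {
    if (is_empty_stratum(e)) {
      stop("empty stratum (group ", e$group, ", country ", e$country,
           "): the group model needs data in both strata", call. = FALSE)
    }
  }
  if (rural$K != urban$K) stop("strata disagree on K", call. = FALSE)
  if (rural$has_dont_know != urban$has_dont_know) {
    stop("strata disagree on the DK option", call. = FALSE)
  }
  K <- rural$K
  if (is.null(priors)) priors <- prior_spec(K)
  stopifnot(priors$K == K)
  has_dk <- rural$has_dont_know
  n_th <- n_free_thresholds(K)
  nm <- param_names_group(K, has_dk)

  counts_r <- encoded_counts(rural); n_ord_r <- sum(counts_r)
  counts_u <- encoded_counts(urban); n_ord_u <- sum(counts_u)

  log_post <- function(par) {
    mu_r <- par[1L]; mu_u <- par[2L]
    sig_r <- par[3L]; sig_u <- par[4L]
    th_free <- if (n_th) par[4L + seq_len(n_th)] else numeric(0)
    d_r <- if (has_dk) par[4L + n_th + 1L] else NULL
    d_u <- if (has_dk) par[4L + n_th + 2L] else NULL
    # independent priors per group; the shared-threshold prior counted once
    lp <- log_prior(mu_r, sig_r, th_free, d_r, priors)
    if (!is.finite(lp)) return(-Inf)
    lp2 <- dunif_log(sig_u, priors$sigma_lower, priors$sigma_upper)
    if (!is.finite(lp2)) return(-Inf)
    lp2 <- lp2 + stats::dnorm(mu_u, priors$mu_mean, priors$mu_sd, log = TRUE)
    if (has_dk) {
      ld <- dunif_log(d_u, priors$delta_lower, priors$delta_upper)
      if (!is.finite(ld)) return(-Inf)
      lp2 <- lp2 + ld
    }
    theta <- make_thresholds(K, th_free)
    p_r <- category_probs(mu_r, sig_r, theta)
    p_u <- category_probs(mu_u, sig_u, theta)
    ll <- loglik_from_counts(counts_r, p_r) + loglik_from_counts(counts_u, p_u)
    if (has_dk) {
      ll <- ll + dk_loglik(rural$dk_count, n_ord_r, d_r) +
        dk_loglik(urban$dk_count, n_ord_u, d_u)
    }
    lp + lp2 + ll
  }

  c_r <- init_center_single(rural)
  c_u <- init_center_single(urban)
  th0 <- if (n_th) seq(2L, K - 2L) + 0.5 else numeric(0)
  center <- c(c_r[1L], c_u[1L], c_r[2L], c_u[2L], th0,
              if (has_dk) c(c_r[length(c_r)], c_u[length(c_u)]))
  delta_idx <- if (has_dk) 4L + n_th + 1:2 else integer(0)
  init <- make_inits(center, control, priors, delta_idx = delta_idx,
                     sigma_idx = 3:4)
  draws <- sample_posterior(log_post, init, control, param_names = nm)
  out <- list(draws = draws, summary = summarize_draws(draws),
              rural = rural, urban = urban, priors = priors,
              control = control, K = K, has_dont_know = has_dk,
              call = match.call())
  class(out) <- "group_fit"
  out
}

#' @export
print.group_fit <- function(x, ...) {
  cat("Latent ordinal model (rural/urban groups, shared thresholds)\n")
  cat("  question '", x$rural$question_id, "', country ", x$rural$country,
      "; n_rural = ", x$rural$n_total, ", n_urban = ", x$urban$n_total,
      ", K = ", x$K, "\n\n", sep = "")
  print(x$summary)
  cat("\nGroup contrasts (urban - rural):\n")
  print(group_contrast(x))
  invisible(x)
}

#' @export
summary.group_fit <- function(object, ...) object$summary

#' @export
coef.group_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
posterior_category_probs.group_fit <- function(object,
                                               level = c("rural", "urban"),
                                               ...) {
  level <- match.arg(level)
  pool <- pool_draws(object$draws)
  nm <- group_param_names(object$K, object$has_dont_know,
                          suffix = if (level == "rural") "R" else "U")
  enc <- if (level == "rural") object$rural else object$urban
  new_category_probs(probs_from_pool(pool, object$K, object$has_dont_know, nm),
                     object$K, object$has_dont_know, level = level,
                     question_id = enc$question_id, country = enc$country,
                     labels = enc_labels(enc))
}

#' Country-level posterior category probabilities by population weighting
#'
#' Balanced panels sample rural and urban respondents in equal numbers, which
#' does not match the countries' actual population split. Country-level
#' answer probabilities are therefore obtained per posterior draw as the
#' convex combination `w_rural * p_rural + (1 - w_rural) * p_urban` of the
#' two groups' (DK-adjusted) category-probability vectors, and summarized
#' over draws. Mixing is linear and per draw, so the posterior mean of the
#' country vector is exactly the weighted combination of the group posterior
#' means.
#'
#' @param fit A [fit_group()] result.
#' @param w_rural The country's rural population proportion in \[0, 1\].
#' @return A `category_probs` object at country level.
#' @export
country_posterior <- function(fit, w_rural) {
  stopifnot(inherits(fit, "group_fit"))
  if (length(w_rural) != 1L || is.na(w_rural) || w_rural < 0 || w_rural > 1) {
    stop("w_rural must be a single proportion in [0, 1]", call. = FALSE)
  }
  pool <- pool_draws(fit$draws)
  pr <- probs_from_pool(pool, fit$K, fit$has_dont_know,
                        group_param_names(fit$K, fit$has_dont_know, "R"))
  pu <- probs_from_pool(pool, fit$K, fit$has_dont_know,
                        group_param_names(fit$K, fit$has_dont_know, "U"))
  new_category_probs(w_rural * pr + (1 - w_rural) * pu,
                     fit$K, fit$has_dont_know, level = "country",
                     question_id = fit$rural$question_id,
                     country = fit$rural$country, w_rural = w_rural,
                     labels = enc_labels(fit$rural))
}

#' @export
predict.group_fit <- function(object, level = c("country", "rural", "urban"),
                              w_rural = NULL, ...) {
  level <- match.arg(level)
  if (level == "country") {
    if (is.null(w_rural)) {
      stop("country-level prediction needs w_rural (the rural population ",
           "proportion)", call. = FALSE)
    }
    country_posterior(object, w_rural)
  } else posterior_category_probs(object, level)
}

#' Posterior rural/urban contrasts
#'
#' Per-draw differences of the group parameters (urban minus rural):
#' `mu_U - mu_R`, `sigma_U - sigma_R` and, where the question has a DK
#' option, `delta_U - delta_R`, summarized with 95% credible intervals, an
#' exclusion-of-zero flag and R-hat.
#'
#' @param fit A [fit_group()] result.
#' @return A `param_summary` data frame of the contrasts.
#' @export
group_contrast <- function(fit) {
  stopifnot(inherits(fit, "group_fit"))
  pairs <- list(c("mu_U", "mu_R"), c("sigma_U", "sigma_R"))
  if (fit$has_dont_know) pairs <- c(pairs, list(c("delta_U", "delta_R")))
  nm <- vapply(pairs, function(p) paste0(p[1], "-", p[2]), "")
  arr <- fit$draws$draws
  d <- dim(arr)
  contr <- array(NA_real_, c(d[1], length(pairs), d[3]),
                 dimnames = list(NULL, nm, NULL))
  for (i in seq_along(pairs)) {
    contr[, i, ] <- arr[, pairs[[i]][1], ] - arr[, pairs[[i]][2], ]
  }
  cd <- fit$draws
  cd$draws <- contr
  cd$param_names <- nm
  summarize_draws(cd)
}

#' @export
plot.group_fit <- function(x, w_rural = NULL, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(w_rural)) 2 else 3))
  on.exit(graphics::par(op))
  plot(posterior_category_probs(x, "rural"), ...)
  plot(posterior_category_probs(x, "urban"), ...)
  if (!is.null(w_rural)) plot(country_posterior(x, w_rural), ...)
  invisible(x)
}

#' @export
simulate.group_fit <- function(object, nsim = 1, seed = NULL,
                               level = c("rural", "urban"), ...) {
  level <- match.arg(level)
  enc <- if (level == "rural") object$rural else object$urban
  simulate_from_pool(pool_draws(object$draws), object$K, object$has_dont_know,
                     enc$n_total, nsim, seed,
                     group_param_names(object$K, object$has_dont_know,
                                       if (level == "rural") "R" else "U"))
}
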