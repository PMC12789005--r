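# Parameter vector layout for a single group's model:
# (mu, sigma, theta2..theta[K-2], delta?) with delta present only when the
# question offers a DK option.

param_names_single <- function(K, has_dk, prefix = "") {
  nm <- c("mu", "sigma",
          if (K > 3L) paste0("theta", seq(2L, K - 2L)))
  nm <- if (prefix == "") nm else paste0(nm, "_", prefix)
  c(nm, if (has_dk) if (prefix == "") "delta" else paste0("delta_", prefix))
}

# Moment-based central init for one group's parameters.
init_center_single <- function(encoded) {
  K <- encoded$K
  codes <- encoded$codes
  mu0 <- if (length(codes)) mean(codes) else (K + 1) / 2
  sd0 <- if (length(codes) > 1L) stats::sd(codes) else 1
  sd0 <- min(max(sd0, 0.3), 3 * K)
  th0 <- if (K > 3L) seq(2L, K - 2L) + 0.5 else numeric(0)
  d0 <- if (encoded$has_dont_know) {
    (encoded$dk_count + 1) / (encoded$n_total + 2)
  } else NULL
  c(mu0, sd0, th0, d0)
}

# Overdispersed per-chain starting points that stay inside the support.
# Deterministic given the control seed.
make_inits <- function(center, control, prior, delta_idx = integer(0),
                       sigma_idx = 2L, theta_spread = 0.08) {
  p <- length(center)
  set.seed(control$seed)
  jit <- matrix(stats::rnorm(control$n_chains * p, sd = 0.15), ncol = p)
  init <- sweep(jit, 2L, center, `+`)
  for (i in sigma_idx) {
    init[, i] <- pmin(pmax(center[i] * exp(jit[, i]),
                           prior$sigma_lower * 1.01),
                      prior$sigma_upper * 0.99)
  }
  # keep free thresholds near their centres and ordered
  theta_idx <- setdiff(seq_len(p), c(sigma_idx, delta_idx))
  theta_idx <- theta_idx[theta_idx > max(sigma_idx)]
  for (i in theta_idx) {
    init[, i] <- center[i] + theta_spread * tanh(jit[, i])
  }
  for (i in delta_idx) {
    init[, i] <- stats::plogis(stats::qlogis(pmin(pmax(center[i], 1e-3),
                                                  1 - 1e-3)) + jit[, i])
  }
  init
}

#' Fit the single-group latent ordinal model
#'
#' Bayesian ordered-probit fit for one stratum: the answers are modelled as a
#' normal latent opinion with mean `mu` and sd `sigma`, cut at thresholds
#' whose extremes are fixed at 1.5 and K - 0.5, with free interior thresholds
#' estimated; questions with an "I don't know" option get a separate DK
#' probability `delta`. Sampling is multi-chain adaptive Metropolis (see
#' [sample_posterior()]).
#'
#' @param encoded An [encode_responses()] object (or from
#'   [simulate_responses()]).
#' @param priors A [prior_spec()]; defaults to `prior_spec(K)`.
#' @param control An [mcmc_control()].
#' @return Object of class `ordinal_fit` with components `draws`
#'   (`posterior_draws`), `summary` (`param_summary`), `encoded`, `priors`,
#'   `control`.
#' @examples
#' \donttest{
#' enc <- simulate_responses(400, mu = 3.2, sigma = 1, K = 5, seed = 7)
#' fit <- fit_ordinal(enc, control = mcmc_control(n_chains = 2,
#'                                                n_iterations = 1500,
#'                                                burn_in = 500, seed = 1))
#' summary(fit)
#' }
#' @export
fit_ordinal <- function(encoded, priors = NULL, control = mcmc_control()) {
  stopifnot(inherits(encoded, "encoded_responses"))
  if (is_empty_stratum(encoded)) {
    stop("empty stratum: no ordinal or DK answers to fit (question '",
         encoded$question_id, "', country ", encoded$country, ", group ",
         encoded$group, ")", call. = FALSE)
  }
  K <- encoded$K
  if (is.null(priors)) priors <- prior_spec(K)
  stopifnot(priors$K == K)
  has_dk <- encoded$has_dont_know
  n_th <- n_free_thresholds(K)
  nm <- param_names_single(K, has_dk)
  counts <- encoded_counts(encoded)
  n_ord <- sum(counts)
  dk_count <- encoded$dk_count

  log_post <- function(par) {
    mu <- par[1L]; sigma <- par[2L]
    th_free <- if (n_th) par[2L + seq_len(n_th)] else numeric(0)
    delta <- if (has_dk) par[length(par)] else NULL
    lp <- log_prior(mu, sigma, th_free, delta, priors)
    if (!is.finite(lp)) return(-Inf)
    p <- category_probs(mu, sigma, make_thresholds(K, th_free))
    ll <- loglik_from_counts(counts, p)
    if (has_dk) ll <- ll + dk_loglik(dk_count, n_ord, delta)
    lp + ll
  }

  center <- init_center_single(encoded)
  init <- make_inits(center, control, priors,
                     delta_idx = if (has_dk) length(nm) else integer(0))
  draws <- sample_posterior(log_post, init, control, param_names = nm)
  out <- list(draws = draws, summary = summarize_draws(draws),
              encoded = encoded, priors = priors, control = control,
              K = K, has_dont_know = has_dk, call = match.call())
  class(out) <- "ordinal_fit"
  out
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Latent ordinal model (single group)\n")
  cat("  question '", x$encoded$question_id, "', country ",
      x$encoded$country, ", group ", x$encoded$group, "; n = ",
      x$encoded$n_total, " (", x$encoded$dk_count, " DK), K = ", x$K,
      "\n\n", sep = "")
  print(x$summary)
  bad <- nonconverged_params(x$summary)
  if (length(bad)) cat("\n  warning: R-hat > 1.1 for",
                       paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ordinal_fit <- function(object, ...) object$summary

#' @export
coef.ordinal_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

# Names of the parameter columns describing one group within a pooled draw
# matrix: mu, sigma, shared thresholds, optional delta.
group_param_names <- function(K, has_dk, suffix = "") {
  sfx <- function(base) if (suffix == "") base else paste0(base, "_", suffix)
  list(mu = sfx("mu"), sigma = sfx("sigma"),
       theta = if (K > 3L) paste0("theta", seq(2L, K - 2L)) else character(0),
       delta = if (has_dk) sfx("delta") else NULL)
}

# Per-draw category-probability matrix from pooled draws.
# Returns (draws x K) or (draws x K+1) with the DK column first.
probs_from_pool <- function(pool, K, has_dk, nm = group_param_names(K, has_dk)) {
  mu <- pool[, nm$mu]
  sigma <- pool[, nm$sigma]
  th <- if (length(nm$theta)) pool[, nm$theta, drop = FALSE] else NULL
  delta <- if (has_dk) pool[, nm$delta] else NULL
  out <- matrix(NA_real_, nrow(pool), K + has_dk)
  for (i in seq_len(nrow(pool))) {
    p <- category_probs(mu[i], sigma[i],
                        make_thresholds(K, if (is.null(th)) numeric(0) else th[i, ]))
    out[i, ] <- if (has_dk) dk_adjust(p, delta[i]) else p
  }
  out
}

new_category_probs <- function(prob_draws, K, has_dk, level, question_id,
                               country = "all", w_rural = NA_real_,
                               labels = NULL) {
  if (is.null(labels)) {
    labels <- c(if (has_dk) "DK", paste0("cat", seq_len(K)))
  }
  colnames(prob_draws) <- labels
  structure(list(
    draws = prob_draws,
    mean = colMeans(prob_draws),
    median = apply(prob_draws, 2, stats::median),
    lower = apply(prob_draws, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(prob_draws, 2, stats::quantile, 0.975, names = FALSE),
    K = K, has_dont_know = has_dk, level = level,
    question_id = question_id, country = country, w_rural = w_rural,
    labels = labels), class = "category_probs")
}

#' @export
print.category_probs <- function(x, digits = 3, ...) {
  cat("Posterior category probabilities (level: ", x$level, ", question '",
      x$question_id, "', country ", x$country, ")\n", sep = "")
  if (!is.na(x$w_rural)) cat("  rural weight:", x$w_rural, "\n")
  tbl <- data.frame(category = x$labels, mean = round(x$mean, digits),
                    median = round(x$median, digits),
                    q2.5 = round(x$lower, digits),
                    q97.5 = round(x$upper, digits), row.names = NULL)
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Tabulate a `category_probs` object
#' @param x A `category_probs` object.
#' @param ... Unused.
#' @return Data frame with one row per answer category.
#' @export
as.data.frame.category_probs <- function(x, ...) {
  data.frame(level = x$level, country = x$country,
             question_id = x$question_id, category = x$labels,
             mean = unname(x$mean), median = unname(x$median),
             lower = unname(x$lower), upper = unname(x$upper),
             stringsAsFactors = FALSE)
}

#' Posterior answer-category probabilities
#'
#' For a fitted model, the posterior distribution of the probability of each
#' answer category (with the DK share first where the question has one),
#' computed per posterior draw and summarized by its mean, median and central
#' 95% interval.
#'
#' @param object A fitted model.
#' @param ... Passed to methods.
#' @return A `category_probs` object.
#' @export
posterior_category_probs <- function(object, ...) {
  UseMethod("posterior_category_probs")
}

#' @export
posterior_category_probs.ordinal_fit <- function(object, ...) {
  pool <- pool_draws(object$draws)
  new_category_probs(probs_from_pool(pool, object$K, object$has_dont_know),
                     object$K, object$has_dont_know,
                     level = object$encoded$group,
                     question_id = object$encoded$question_id,
                     country = object$encoded$country,
                     labels = enc_labels(object$encoded))
}

#' @export
predict.ordinal_fit <- function(object, ...) {
  posterior_category_probs(object)
}

#' @export
simulate.ordinal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_from_pool(pool_draws(object$draws), object$K,
                     object$has_dont_know, object$encoded$n_total,
                     nsim, seed)
}

# Posterior-predictive simulation shared by the fit classes: each replicate
# picks one pooled draw and simulates a response vector of length n from it.
simulate_from_pool <- function(pool, K, has_dk, n, nsim, seed,
                               nm = group_param_names(K, has_dk)) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(pool), nsim, replace = TRUE)
  lapply(idx, function(i) {
    th_free <- if (length(nm$theta)) pool[i, nm$theta] else numeric(0)
    simulate_responses(n, mu = pool[i, nm$mu], sigma = pool[i, nm$sigma],
                       K = K, theta_free = th_free,
                       delta = if (has_dk) pool[i, nm$delta] else 0)
  })
}

#' @export
plot.ordinal_fit <- function(x, ...) {
  plot(posterior_category_probs(x), ...)
}

#' @export
plot.category_probs <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- paste0(x$question_id, " (", x$country, ", ", x$level, ")")
  }
  mid <- graphics::barplot(x$mean, names.arg = x$labels,
                           ylim = c(0, min(1, max(x$upper) * 1.15)),
                           ylab = "posterior probability", main = main, ...)
  graphics::segments(mid, x$lower, mid, x$upper)
  invisible(x)
}
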