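#' MCMC sampler configuration
#'
#' Defaults follow common practice for these models: six chains, 10,000
#' iterations with the first 5,000 discarded as burn-in, no thinning.
#'
#' @param n_chains Number of chains (>= 2, required by the Gelman-Rubin
#'   diagnostic).
#' @param n_iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain
#'   (< `n_iterations`). Proposal adaptation is confined to the burn-in so the
#'   post-burn-in transition kernel is fixed.
#' @param thin Keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed Integer seed; chain c uses `seed + c`. Identical seed, inits
#'   and configuration give bit-identical draws.
#' @param proposal_scales Optional positive numeric vector of initial
#'   random-walk proposal standard deviations, one per parameter (recycled).
#' @param adapt Adapt proposal scales (and block covariance) during burn-in.
#' @return Object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 6L, n_iterations = 10000L,
                         burn_in = 5000L, thin = 1L, seed = 1L,
                         proposal_scales = NULL, adapt = TRUE) {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(n_chains >= 2L, n_iterations >= 2L, burn_in >= 0L,
            burn_in < n_iterations, thin >= 1L)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 burn_in = burn_in, thin = thin, seed = as.integer(seed),
                 proposal_scales = proposal_scales, adapt = isTRUE(adapt)),
            class = "mcmc_control")
}

#' Draw posterior samples with adaptive random-walk Metropolis
#'
#' Generic multi-chain sampler over an arbitrary log-posterior. Parameters
#' are updated in blocks (Metropolis-within-Gibbs); each scalar block uses a
#' normal random walk whose scale is tuned towards a 44% acceptance rate
#' during burn-in, and multi-parameter blocks use a multivariate normal
#' proposal whose covariance is estimated from the burn-in history (tuned
#' towards 23% acceptance). Adaptation stops at the end of burn-in, so the
#' retained draws come from a fixed Markov kernel. Support constraints are
#' enforced by rejection: the log-posterior returns `-Inf` outside support.
#'
#' @param log_post Function mapping a parameter vector to a log-posterior
#'   value (finite or `-Inf`; `NaN` is a hard error).
#' @param init Initial parameter values: a numeric vector used for every
#'   chain, or a matrix with one row per chain. `log_post` must be finite at
#'   every initial point.
#' @param control An [mcmc_control()].
#' @param param_names Optional parameter names.
#' @param blocks Optional list of integer vectors partitioning the parameter
#'   indices into update blocks; default is one block per parameter.
#' @return Object of class `posterior_draws`: retained draws in an array
#'   `[iteration, parameter, chain]` with the control and acceptance rates
#'   attached.
#' @export
sample_posterior <- function(log_post, init, control = mcmc_control(),
                             param_names = NULL, blocks = NULL) {
  if (is.null(dim(init))) init <- matrix(init, nrow = control$n_chains,
                                         ncol = length(init), byrow = TRUE)
  if (nrow(init) != control$n_chains) {
    stop("init must have one row per chain", call. = FALSE)
  }
  p <- ncol(init)
  if (is.null(param_names)) param_names <- paste0("par", seq_len(p))
  if (is.null(blocks)) blocks <- as.list(seq_len(p))
  scales0 <- control$proposal_scales
  if (is.null(scales0)) scales0 <- rep(0.1, p) else scales0 <- rep_len(scales0, p)
  stopifnot(all(scales0 > 0))

  n_keep <- (control$n_iterations - control$burn_in) %/% control$thin
  if (n_keep < 1L) stop("no draws retained: increase n_iterations", call. = FALSE)
  draws <- array(NA_real_, dim = c(n_keep, p, control$n_chains),
                 dimnames = list(NULL, param_names, NULL))
  accept <- matrix(0, length(blocks), control$n_chains)

  eval_lp <- function(x) {
    lp <- log_post(x)
    if (length(lp) != 1L || is.nan(lp) || (is.na(lp) && !is.nan(lp))) {
      stop("log-posterior returned NaN/NA at parameters (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    }
    lp
  }

  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + ch)
    x <- as.numeric(init[ch, ])
    lp <- eval_lp(x)
    if (!is.finite(lp)) {
      stop("chain ", ch, ": log-posterior is not finite at the initial values",
           call. = FALSE)
    }
    log_s <- log(scales0)                 # per-parameter scalar scales
    blk_log_s <- vapply(blocks, function(b) mean(log_s[b]), 0)
    blk_chol <- vector("list", length(blocks))   # frozen after burn-in
    n_acc <- n_try <- rep(0, length(blocks))
    batch_acc <- batch_try <- rep(0, length(blocks))
    hist_n <- min(control$burn_in, 2000L)
    hist <- if (control$burn_in > 0L) matrix(NA_real_, hist_n, p)
    kept <- 0L

    for (it in seq_len(control$n_iterations)) {
      in_burn <- it <= control$burn_in
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        prop <- x
        if (length(b) == 1L) {
          prop[b] <- x[b] + exp(log_s[b]) * stats::rnorm(1)
        } else if (!is.null(blk_chol[[bi]])) {
          prop[b] <- x[b] + exp(blk_log_s[bi]) *
            drop(stats::rnorm(length(b)) %*% blk_chol[[bi]])
        } else {
          prop[b] <- x[b] + exp(blk_log_s[bi]) * stats::rnorm(length(b))
        }
        lp_prop <- eval_lp(prop)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
        if (acc) { x <- prop; lp <- lp_prop }
        n_try[bi] <- n_try[bi] + 1
        batch_try[bi] <- batch_try[bi] + 1
        if (acc) { n_acc[bi] <- n_acc[bi] + 1; batch_acc[bi] <- batch_acc[bi] + 1 }
      }
      if (in_burn) {
        hist[((it - 1L) %% hist_n) + 1L, ] <- x
        if (control$adapt && it %% 50L == 0L) {
          step <- min(0.25, 3 / sqrt(it))
          for (bi in seq_along(blocks)) {
            target <- if (length(blocks[[bi]]) == 1L) 0.44 else 0.234
            rate <- batch_acc[bi] / max(1, batch_try[bi])
            adj <- if (rate > target) step else -step
            if (length(blocks[[bi]]) == 1L) {
              log_s[blocks[[bi]]] <- log_s[blocks[[bi]]] + adj
            } else blk_log_s[bi] <- blk_log_s[bi] + adj
          }
          batch_acc[] <- 0; batch_try[] <- 0
          if (it >= 300L && it %% 200L == 0L) {
            rows <- seq_len(min(it, hist_n))
            for (bi in seq_along(blocks)) {
              b <- blocks[[bi]]
              if (length(b) > 1L) {
                cv <- stats::cov(hist[rows, b, drop = FALSE])
                cv <- cv + diag(1e-8 + 1e-6 * mean(diag(cv)), length(b))
                ch_ok <- tryCatch(chol(cv), error = function(e) NULL)
                if (!is.null(ch_ok)) blk_chol[[bi]] <- ch_ok
              }
            }
          }
        }
        if (it == control$burn_in) {
          # freeze: any block without an estimated covariance keeps identity
          n_acc[] <- 0; n_try[] <- 0
        }
      } else if ((it - control$burn_in) %% control$thin == 0L) {
        kept <- kept + 1L
        if (kept <= n_keep) draws[kept, , ch] <- x
      }
    }
    accept[, ch] <- n_acc / pmax(1, n_try)
  }

  structure(list(draws = draws, param_names = param_names, control = control,
                 blocks = blocks, accept_rate = accept),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior draws: ", d[2], " parameters, ", d[3], " chains x ", d[1],
      " retained iterations\n", sep = "")
  cat("  parameters: ", paste(x$param_names, collapse = ", "), "\n", sep = "")
  cat("  mean acceptance rate: ", round(mean(x$accept_rate), 3), "\n", sep = "")
  invisible(x)
}

#' Export posterior draws as a long table
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return Data frame with columns `chain`, `iteration`, `parameter`, `value`,
#'   suitable for external diagnostics.
#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  data.frame(
    chain = rep(seq_len(d[3]), each = d[1] * d[2]),
    iteration = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    parameter = rep(rep(x$param_names, each = d[1]), times = d[3]),
    value = as.vector(x$draws),
    stringsAsFactors = FALSE)
}

# Pool all chains into a (draws x parameters) matrix.
pool_draws <- function(x) {
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(1, 3, 2)), d[1] * d[3], d[2])
  colnames(m) <- x$param_names
  m
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic (non-split) diagnostic. With m chains of n retained draws, W is
#' the mean within-chain variance, B/n the variance of the chain means,
#' `Vhat = ((n - 1)/n) W + B/n`, and `Rhat = sqrt(Vhat / W)`, computed per
#' parameter. Values near 1 indicate the chains are sampling the same
#' distribution.
#'
#' @param x A `posterior_draws` object, or a numeric matrix/array with one
#'   column (or slice) per chain for a single parameter.
#' @param on_undefined What to do when every chain has zero within-chain
#'   variance (the diagnostic is undefined): raise a classed error
#'   (`"surveyprobit_rhat_undefined"`) or return `NA` with a warning.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(x, on_undefined = c("error", "na")) {
  on_undefined <- match.arg(on_undefined)
  if (inherits(x, "posterior_draws")) {
    arr <- x$draws
  } else if (is.matrix(x)) {
    arr <- array(x, dim = c(nrow(x), 1L, ncol(x)),
                 dimnames = list(NULL, "par1", NULL))
  } else arr <- x
  d <- dim(arr)
  if (d[3] < 2L || d[1] < 2L) {
    stop("need at least 2 chains with at least 2 draws each", call. = FALSE)
  }
  n <- d[1]
  out <- stats::setNames(numeric(d[2]), dimnames(arr)[[2]])
  for (j in seq_len(d[2])) {
    ch <- arr[, j, , drop = TRUE]
    W <- mean(apply(ch, 2, stats::var))
    if (W == 0) {
      msg <- paste0("Gelman-Rubin undefined for '", dimnames(arr)[[2]][j],
                    "': zero within-chain variance in all chains")
      if (on_undefined == "error") {
        stop(structure(class = c("surveyprobit_rhat_undefined", "error",
                                 "condition"),
                       list(message = msg, call = NULL)))
      }
      warning(msg, call. = FALSE)
      out[j] <- NA_real_
      next
    }
    B <- n * stats::var(colMeans(ch))
    v_hat <- (n - 1) / n * W + B / n
    out[j] <- sqrt(v_hat / W)
  }
  out
}

#' Summarize posterior draws
#'
#' Pools all chains and reports, per parameter, the posterior mean, sd,
#' 2.5%/50%/97.5% quantiles, the Gelman-Rubin R-hat and whether the central
#' 95% credible interval excludes zero.
#'
#' @param x A `posterior_draws` object.
#' @return Data frame of class `param_summary` with one row per parameter.
#' @export
summarize_draws <- function(x) {
  m <- pool_draws(x)
  rhat <- suppressWarnings(gelman_rubin(x, on_undefined = "na"))
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE, type = 7))
  out <- data.frame(
    parameter = x$param_names,
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
    rhat = as.numeric(rhat),
    ci_excludes_zero = qs[, 1] > 0 | qs[, 3] < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("param_summary", "data.frame")
  out
}

#' @export
print.param_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Flag parameters that have not converged
#'
#' @param x A `posterior_draws` or `param_summary`.
#' @param threshold R-hat threshold above which a parameter is flagged
#'   (default 1.1).
#' @return Character vector of parameter names with R-hat above the threshold.
#' @export
nonconverged_params <- function(x, threshold = 1.1) {
  s <- if (inherits(x, "param_summary")) x else summarize_draws(x)
  s$parameter[!is.na(s$rhat) & s$rhat > threshold]
}
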