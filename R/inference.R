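#' Default likelihood hyperparameters and priors
#'
#' The sampling model uses two data channels per observation: the
#' instability direction, read from the blurriness via the printed
#' thresholds (`B > 0.5` out-of-plane, `B <= 0.05` in-plane, intermediate
#' rows treated as mixed and down-weighted), and optionally the
#' wavelength.  The direction channel is a Bernoulli with
#' `P(out) = logistic(s * log(sigma_h*/sigma_y*))`; the wavelength channel
#' is Gaussian on the log scale.  `s` and `sigma_lambda` are fixed
#' hyperparameters so the model keeps exactly four free parameters.
#'
#' Priors: log-uniform over six decades (1e-2 to 1e4) for each of the
#' three kinetic ratios, uniform(0, 1) for p0.
#'
#' @return A list of hyperparameters (`s`, `sigma_lambda`, `b_in`,
#'   `b_out`, `eps`, `KM`, `length_exponent`, `gamma`, `use_wavelength`)
#'   and prior bounds (`log_ratio_bounds`).
#' @examples
#' default_inference_hyper()
#' @export
default_inference_hyper <- function() {
  list(s = 5, sigma_lambda = 0.2, b_in = 0.05, b_out = 0.5, eps = 1e-6,
       KM = 30, length_exponent = 2, gamma = 1, use_wavelength = TRUE,
       log_ratio_bounds = log(c(1e-2, 1e4)))
}

# theta = (log r_zeta_mu, log r_K_kappa, log r_kappa_zeta, logit p0)
theta_to_constants <- function(theta, hyper) {
  kinetic_constants_from_ratios(exp(theta[1]), exp(theta[2]), exp(theta[3]),
                                p0 = stats::plogis(theta[4]),
                                KM = hyper$KM,
                                length_exponent = hyper$length_exponent)
}

#' Log-likelihood of phase-diagram observations
#'
#' @param theta numeric 4-vector: `log(zeta0/mu0)`, `log(K0/kappa0)`,
#'   `log(kappa0/zeta0)`, `logit(p0)`.
#' @param data a data frame with columns `atp`, `motors`, `prc1`,
#'   `mt_length`, `B` and optionally `lambda_obs` (as produced by
#'   [generate_phase_observations()]).
#' @param hyper hyperparameter list, see [default_inference_hyper()].
#' @return The log-likelihood (finite for finite `theta` and valid data).
#'   Only the three ratios and p0 enter, so the likelihood is invariant to
#'   a common rescaling of all four prefactors.
#' @examples
#' obs <- generate_phase_observations(default_generator_config(4, 4), seed = 1)
#' log_likelihood(c(log(1200), log(200), log(0.5), qlogis(0.6)), obs)
#' @export
log_likelihood <- function(theta, data, hyper = default_inference_hyper()) {
  if (length(theta) != 4 || any(!is.finite(theta)))
    stop("log_likelihood: theta must be a finite 4-vector")
  if (nrow(data) == 0) stop("log_likelihood: empty data")
  k <- theta_to_constants(theta, hyper)
  comp <- composition(data$atp, data$motors, data$prc1, data$mt_length)
  mt <- mechanics_table(comp, k, hyper$gamma)
  eps <- hyper$eps

  # direction channel
  lr <- log(mt$sigma_h_star) - log(mt$sigma_y_star)   # +Inf if only h grows
  p_out <- ifelse(mt$sigma_h_star == 0 & mt$sigma_y_star == 0, 0.5,
           ifelse(mt$sigma_y_star == 0, 1 - eps,
           ifelse(mt$sigma_h_star == 0, eps,
                  stats::plogis(hyper$s * lr))))
  p_out <- pmin(pmax(p_out, eps), 1 - eps)
  mixed <- data$B > hyper$b_in & data$B <= hyper$b_out
  y <- ifelse(data$B > hyper$b_out, 1,
       ifelse(mixed, as.numeric(data$B > (hyper$b_in + hyper$b_out) / 2), 0))
  w <- ifelse(mixed, 0.5, 1)
  ll <- sum(w * (y * log(p_out) + (1 - y) * log(1 - p_out)))

  # wavelength channel: mixture over the two branch wavelengths weighted
  # by the direction probability (rows where data and model define one).
  # The mixture keeps the likelihood continuous where a cell's winning
  # branch flips as theta moves; a hard winning-branch Gaussian would
  # jump there, leaving the posterior riddled with row-level steps.
  if (isTRUE(hyper$use_wavelength) && "lambda_obs" %in% names(data)) {
    ll <- ll + wavelength_mixture_ll(log(data$lambda_obs),
                                     log(mt$lambda_h), log(mt$lambda_y),
                                     p_out, hyper$sigma_lambda)
  }
  ll
}

# Sum over rows of log[ p_out N(x | log lambda_h, s) +
#                       (1 - p_out) N(x | log lambda_y, s) ],
# dropping branches the model declares stable (NA wavelength) and rows
# with no observed or no predicted wavelength.
wavelength_mixture_ll <- function(x, lh, ly, p_out, sigma) {
  dh <- ifelse(is.finite(lh), stats::dnorm(x, lh, sigma), 0)
  dy <- ifelse(is.finite(ly), stats::dnorm(x, ly, sigma), 0)
  mix <- p_out * dh + (1 - p_out) * dy
  ok <- is.finite(x) & (is.finite(lh) | is.finite(ly))
  sum(log(pmax(mix[ok], .Machine$double.xmin)))
}

# Precompiled fast likelihood: same model as log_likelihood(), with the
# data-dependent quantities (stepping fraction, direction labels, weights)
# hoisted out of the per-step evaluation.  log_likelihood() remains the
# reference implementation; the two are asserted equal in the test suite.
make_log_likelihood <- function(data, hyper) {
  f <- data$atp / (hyper$KM + data$atp)
  motors <- data$motors; prc1 <- data$prc1
  La <- data$mt_length^hyper$length_exponent
  mixed <- data$B > hyper$b_in & data$B <= hyper$b_out
  y <- ifelse(data$B > hyper$b_out, 1,
       ifelse(mixed, as.numeric(data$B > (hyper$b_in + hyper$b_out) / 2), 0))
  w <- ifelse(mixed, 0.5, 1)
  has_lam <- isTRUE(hyper$use_wavelength) && "lambda_obs" %in% names(data)
  log_lam <- if (has_lam) log(data$lambda_obs) else NULL
  eps <- hyper$eps; s <- hyper$s; g <- hyper$gamma; sl <- hyper$sigma_lambda
  function(theta) {
    r_zm <- exp(theta[1]); r_Kk <- exp(theta[2]); r_kz <- exp(theta[3])
    p0 <- stats::plogis(theta[4])
    zeta <- motors * f                       # zeta0 = 1 scale
    xl2 <- (p0 * prc1 + motors * (1 - f))^2
    mu <- xl2 / r_zm
    kappa <- r_kz * xl2
    K <- r_Kk * r_kz * La
    sig_y <- ifelse(zeta > mu, (zeta - mu)^2 / (4 * g * K), 0)
    sig_h <- ifelse(zeta > 0, zeta^2 / (4 * g * (K + kappa)), 0)
    p_out <- ifelse(sig_h == 0 & sig_y == 0, 0.5,
             ifelse(sig_y == 0, 1 - eps,
             ifelse(sig_h == 0, eps,
                    stats::plogis(s * (log(sig_h) - log(sig_y))))))
    p_out <- pmin(pmax(p_out, eps), 1 - eps)
    ll <- sum(w * (y * log(p_out) + (1 - y) * log(1 - p_out)))
    if (has_lam) {
      lh <- ifelse(sig_h > 0, log(2 * pi) - 0.5 * log(zeta / (2 * (K + kappa))),
                   NA_real_)
      ly <- ifelse(sig_y > 0, log(2 * pi) - 0.5 * log(pmax(zeta - mu, 0) / (2 * K)),
                   NA_real_)
      ll <- ll + wavelength_mixture_ll(log_lam, lh, ly, p_out, sl)
    }
    ll
  }
}

log_prior <- function(theta, hyper) {
  b <- hyper$log_ratio_bounds
  if (any(theta[1:3] < b[1]) || any(theta[1:3] > b[2])) return(-Inf)
  p <- stats::plogis(theta[4])
  # uniform(0,1) on p0 expressed on the logit scale (Jacobian p(1-p))
  log(p) + log1p(-p)
}

draw_from_prior <- function(hyper) {
  b <- hyper$log_ratio_bounds
  c(runif(3, b[1], b[2]), stats::qlogis(runif(1)))
}

#' Posterior sampling of the four kinetic parameters by adaptive MCMC
#'
#' Adaptive random-walk Metropolis (Haario-style: proposal covariance
#' adapted to the running chain covariance, global scale tuned toward an
#' acceptance rate of 0.234 during the first half, which is then discarded
#' as burn-in).  Runs `n_chains` independent chains from overdispersed
#' prior draws; fully reproducible given `seed`.
#'
#' @param data observation data frame, see [log_likelihood()].
#' @param n_chains number of chains (>= 2 so convergence can be assessed).
#' @param n_steps iterations per chain (>= 1000 recommended for real use).
#' @param seed integer seed (mandatory).
#' @param hyper hyperparameters and priors, see [default_inference_hyper()].
#' @param init optional 4-vector of starting values (all chains jittered
#'   around it).  By default a cheap posterior-mode search (best of
#'   `n_starts` prior draws, refined by Nelder-Mead) locates the starting
#'   point: the posterior is typically very concentrated relative to the
#'   six-decade prior, and random-walk chains started from the prior bulk
#'   would spend most of their budget finding it.
#' @param n_starts prior draws scored in the mode search.
#' @return An object of class `posterior_summary`: `summary` data frame
#'   (posterior mean/median/2.5%/97.5% per parameter, on the natural
#'   scale: the three ratios and p0), `draws` (post-burn-in array
#'   iterations x 4 x chains, transformed scale), `acceptance_rate`,
#'   `rhat` (split R-hat per parameter) and `convergence_warning`.
#' @examples
#' obs <- generate_phase_observations(default_generator_config(4, 4), seed = 1)
#' fit <- run_mcmc(obs, n_chains = 2, n_steps = 400, seed = 2)
#' fit$summary
#' @export
run_mcmc <- function(data, n_chains = 4, n_steps = 5000, seed,
                     hyper = default_inference_hyper(), init = NULL,
                     n_starts = 100) {
  if (missing(seed)) stop("run_mcmc: seed is mandatory")
  if (n_chains < 2) stop("run_mcmc: n_chains must be >= 2")
  par_names <- c("r_zeta_mu", "r_K_kappa", "r_kappa_zeta", "p0")
  flat <- nrow(data) == 0    # empty data: sample the prior
  ll_fun <- if (flat) function(th) 0 else make_log_likelihood(data, hyper)
  log_post <- function(th) {
    lp <- log_prior(th, hyper)
    if (!is.finite(lp)) return(-Inf)
    lp + ll_fun(th)
  }
  draws <- array(NA_real_, c(n_steps, 4, n_chains))
  n_accept <- 0
  burn <- floor(n_steps / 2)
  with_preserved_seed(seed, {
    if (is.null(init)) {
      # multistart mode search: the posterior is sharply peaked inside a
      # six-decade prior and can carry minor local optima, so refine the
      # best few of many cheap prior draws and keep the overall winner
      starts <- replicate(n_starts, draw_from_prior(hyper))
      lps <- apply(starts, 2, log_post)
      if (flat) {
        init <- starts[, which.max(lps)]
      } else {
        top <- order(lps, decreasing = TRUE)[seq_len(min(5, n_starts))]
        cand <- lapply(top, function(j)
          stats::optim(starts[, j], log_post, method = "Nelder-Mead",
                       control = list(fnscale = -1, maxit = 500)))
        init <- cand[[which.max(vapply(cand, `[[`, 0, "value"))]]$par
      }
    }
    for (ch in seq_len(n_chains)) {
      th <- init + rnorm(4, 0, 0.1)
      lp <- log_post(th)
      while (!is.finite(lp)) { th <- init + rnorm(4, 0, 0.02); lp <- log_post(th) }
      cov_chol <- chol(diag(0.01, 4))
      log_scale <- 0
      run_mean <- th
      run_cov <- diag(0.01, 4)
      for (i in seq_len(n_steps)) {
        prop <- th + exp(log_scale) * drop(rnorm(4) %*% cov_chol)
        lpp <- log_post(prop)
        acc <- is.finite(lpp) && log(runif(1)) < lpp - lp
        if (acc) { th <- prop; lp <- lpp }
        n_accept <- n_accept + acc
        if (i <= burn) {
          # adapt only during the (discarded) first half: running chain
          # covariance (Haario) plus constant-gain global scale tuning
          dlt <- th - run_mean
          run_mean <- run_mean + dlt / (i + 1)
          run_cov <- run_cov * (i / (i + 1)) + tcrossprod(dlt) * (i / (i + 1)^2)
          if (i >= 50 && i %% 25 == 0)
            cov_chol <- chol((2.38^2 / 4) * (run_cov + diag(1e-10, 4)))
          log_scale <- log_scale + 0.05 * (acc - 0.234)
        }
        draws[i, , ch] <- th
      }
    }
  })
  keep <- (burn + 1):n_steps
  post <- draws[keep, , , drop = FALSE]
  acc_rate <- n_accept / (n_steps * n_chains)
  if (acc_rate < 0.05 || acc_rate > 0.8)
    warning(sprintf("run_mcmc: acceptance rate %.2f outside [0.05, 0.8]",
                    acc_rate))
  rhat <- vapply(1:4, function(j) split_rhat(post[, j, ]), numeric(1))
  names(rhat) <- par_names
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("run_mcmc: R-hat > 1.1 for ",
            paste(par_names[which(rhat > 1.1)], collapse = ", "),
            "; chains may not have converged")
  natural <- function(j, x) if (j == 4) stats::plogis(x) else exp(x)
  summ <- do.call(rbind, lapply(1:4, function(j) {
    x <- natural(j, as.vector(post[, j, ]))
    data.frame(parameter = par_names[j], mean = mean(x),
               median = median(x),
               q2.5 = quantile(x, 0.025, names = FALSE),
               q97.5 = quantile(x, 0.975, names = FALSE),
               rhat = rhat[j])
  }))
  structure(list(summary = summ, draws = post,
                 par_names = par_names,
                 acceptance_rate = acc_rate, rhat = rhat,
                 convergence_warning = any(rhat > 1.1, na.rm = TRUE),
                 hyper = hyper),
            class = "posterior_summary")
}

# split R-hat (Gelman-Rubin on split chains) for one parameter;
# x: iterations x chains
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[1:half, , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior over %d chains (acceptance %.2f)%s:\n",
              dim(x$draws)[3], x$acceptance_rate,
              if (x$convergence_warning) " [convergence warning]" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive phase boundary with credible band
#'
#' Evaluates [boundary_trace()] over a thinned subsample of posterior
#' draws and summarises, per scan line and crossing index, the pointwise
#' 2.5/50/97.5 percentiles of the boundary position.
#'
#' @param fit a `posterior_summary` from [run_mcmc()].
#' @param axis1,axis2,fixed,gamma,max_crossings passed to
#'   [boundary_trace()].
#' @param n_draws number of (evenly thinned) posterior draws to use.
#' @return Data frame with `<axis1 name>`, `crossing`, `lo`, `med`, `hi`
#'   (the axis2 position of the boundary).
#' @examples
#' obs <- generate_phase_observations(default_generator_config(4, 4), seed = 1)
#' fit <- run_mcmc(obs, n_chains = 2, n_steps = 400, seed = 2)
#' bb <- posterior_predictive_boundary(fit,
#'         list(name = "prc1", values = c(100, 300)),
#'         list(name = "atp", values = 10^seq(0, 3.2, length.out = 40)),
#'         fixed = list(motors = 60, mt_length = 1.5), n_draws = 10)
#' @export
posterior_predictive_boundary <- function(fit, axis1, axis2, fixed,
                                          gamma = 1, n_draws = 50,
                                          max_crossings = 2) {
  stopifnot(inherits(fit, "posterior_summary"))
  d <- fit$draws
  flat <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch]))
  idx <- unique(round(seq(1, nrow(flat), length.out = n_draws)))
  pieces <- lapply(idx, function(i) {
    k <- theta_to_constants(flat[i, ], fit$hyper)
    b <- boundary_trace(axis1, axis2, fixed, k, gamma,
                        max_crossings = max_crossings)
    if (nrow(b) > 0) b$draw <- i
    b
  })
  all_b <- do.call(rbind, pieces[vapply(pieces, nrow, 0L) > 0])
  if (is.null(all_b) || nrow(all_b) == 0)
    return(stats::setNames(data.frame(numeric(0), integer(0), numeric(0),
                                      numeric(0), numeric(0)),
                           c(axis1$name, "crossing", "lo", "med", "hi")))
  sp <- split(all_b[[axis2$name]],
              interaction(all_b[[axis1$name]], all_b$crossing,
                          sep = "|", drop = TRUE))
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    key <- strsplit(nm, "|", fixed = TRUE)[[1]]
    v <- sp[[nm]]
    data.frame(a1 = as.numeric(key[1]), crossing = as.integer(key[2]),
               lo = quantile(v, 0.025, names = FALSE),
               med = median(v),
               hi = quantile(v, 0.975, names = FALSE))
  }))
  names(out)[1] <- axis1$name
  rownames(out) <- NULL
  out[order(out$crossing, out[[axis1$name]]), ]
}
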