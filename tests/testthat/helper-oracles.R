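# Independent numeric oracles the closed forms are checked against.

# Brute-force most-unstable mode: argmax of the dispersion relation on a
# composite log + linear wavenumber grid spanning the analytic scale.
grid_argmax_mode <- function(p, branch, n_grid = 1e4) {
  drive <- if (branch == "in_plane") p$zeta - p$mu else p$zeta
  stiff <- if (branch == "in_plane") p$K else p$K + p$kappa
  q_scale <- sqrt(max(drive, stiff) / max(stiff, .Machine$double.eps))
  qs <- sort(unique(c(10^seq(log10(1e-3 * q_scale), log10(10 * q_scale),
                             length.out = n_grid / 2),
                      seq(1e-3 * q_scale, 10 * q_scale,
                          length.out = n_grid / 2))))
  sig <- if (branch == "in_plane") growth_rate_in_plane(p, qs)
         else growth_rate_out_of_plane(p, qs)
  i <- which.max(sig)
  list(q_star = qs[i], sigma_star = sig[i], unstable = sig[i] > 0)
}

# Bisection on sigma_y*(zeta) = sigma_h*(zeta) at fixed mu, K, kappa:
# the activity ratio above which the in-plane bend outgrows the buckle.
bisect_critical_ratio <- function(kappa_over_K, mu = 1, K = 1, gamma = 1,
                                  tol = 1e-12) {
  kappa <- kappa_over_K * K
  diff_sig <- function(zeta) {
    sy <- if (zeta > mu) (zeta - mu)^2 / (4 * gamma * K) else 0
    sh <- zeta^2 / (4 * gamma * (K + kappa))
    sy - sh
  }
  lo <- mu * (1 + 1e-12)
  hi <- mu * 1e6
  stopifnot(diff_sig(lo) < 0, diff_sig(hi) > 0)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (diff_sig(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / mid < tol) break
  }
  0.5 * (lo + hi) / mu
}

# Random unstable-elastomer draws for property-style suites.
random_params <- function(require_in_plane_unstable = FALSE) {
  repeat {
    p <- elastomer_params(zeta = runif(1, 0.1, 10),
                          mu = runif(1, 0.05, 5),
                          kappa = runif(1, 0.05, 5),
                          K = runif(1, 0.05, 5),
                          gamma = runif(1, 0.2, 5))
    if (!require_in_plane_unstable || p$zeta > p$mu) return(p)
  }
}
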