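# Worked parameter set used throughout: proliferative branch (N* = 1,
# C_P* = 2, IPPI = 2), quiescent branch (N = 2, IPPI = 1).
worked_params <- function() kinetic_params(k1 = 2, k2 = 1, kd1 = 1,
                                           k3 = 4, k4 = 2, kd2 = 1)

# Log-uniform sampler over [lo, hi] per rate constant. Returns a list of
# kinetic_params. Filters optionally to sets with a feasible, non-negative
# proliferative branch (k1 > kd1 and algebraic C_P* >= 0), resampling until
# n qualify.
random_params <- function(n, seed, lo = 0.1, hi = 10,
                          require_proliferative = FALSE) {
  set.seed(seed)
  draw <- function() {
    v <- exp(runif(6, log(lo), log(hi)))
    kinetic_params(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  out <- list()
  while (length(out) < n) {
    p <- draw()
    if (require_proliferative) {
      if (p$k1 <= p$kd1) next
      if (steady_state_cp(p, steady_state_n(p)) < 0) next
    }
    out[[length(out) + 1]] <- p
  }
  out
}

rate_names_for_tests <- function() c("k1", "k2", "kd1", "k3", "k4", "kd2")

# Build a parameter set whose proliferative steady state sits at a given
# IPPI with baseline NADH N0 (inverse construction used by algebra checks).
params_with_ippi <- function(ippi, N0 = 1, k4 = 2, kd2 = 1,
                             pool_total = 1000) {
  # N* = N0 requires kd1 k2/(k1 - kd1) = N0; pick kd1 = 1, k1 = 2, k2 = N0
  kinetic_params(k1 = 2, k2 = N0, kd1 = 1,
                 k3 = ippi * k4 * kd2 * N0, k4 = k4, kd2 = kd2,
                 pool_total = pool_total)
}
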