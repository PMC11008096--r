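# Master finite-difference oracle: verifies analytic Cartesian and
# extended-variable derivatives of every energy term against central
# differences on a fixture, over randomized states.

#' Finite-difference check of all analytic derivatives
#'
#' For each random state: the titration/tautomer variables are drawn
#' uniformly in `[0.1, 0.9]`, coordinates are jittered, and a subset of
#' Cartesian coordinates plus every extended variable is checked per energy
#' term.  Relative error uses `|fd - an| / max(|fd|, |an|, floor)` with a
#' 1e-3 kcal/mol floor so exact zeros compare at absolute precision.
#'
#' @param fixture result of [make_fixture()] (or a list with `system`,
#'   `config`).
#' @param n_states number of random states.
#' @param n_coords Cartesian coordinates checked per state.
#' @param h_x,h_lz central-difference steps.
#' @param jitter coordinate jitter amplitude (Angstrom).
#' @param seed RNG seed.
#' @return named vector of max relative errors per term and derivative
#'   class (`<term>_x`, `<term>_lz`).
#' @export
check_gradients <- function(fixture, n_states = 5, n_coords = 2,
                            h_x = 1e-4, h_lz = 1e-5, jitter = 0.05,
                            seed = 1) {
  set.seed(seed)
  sys0 <- fixture$system
  cfg <- fixture$config
  cfg$scf_tol <- 1e-11
  nth <- sys0$n_theta %||% 0L
  worst <- numeric(0)
  bump <- function(name, err) {
    if (is.null(worst[name]) || is.na(worst[name]) || err > worst[name])
      worst[name] <<- err
  }
  floor_ <- 1e-3
  for (st in seq_len(n_states)) {
    sys <- sys0
    if (sys$n > 0)
      sys$xyz <- sys$xyz + matrix(stats::rnorm(3 * sys$n, 0, jitter),
                                  sys$n, 3)
    lz <- if (nth > 0) stats::runif(nth, 0.1, 0.9) else numeric(0)
    an <- cph_energy(sys, lz, cfg, gradient = TRUE)
    if (sys$n > 0) {
      for (pick in seq_len(n_coords)) {
        i <- sample(sys$n, 1); g <- sample(3, 1)
        ep <- em <- sys
        ep$xyz[i, g] <- ep$xyz[i, g] + h_x
        em$xyz[i, g] <- em$xyz[i, g] - h_x
        Ep <- cph_energy(ep, lz, cfg, gradient = FALSE)
        Em <- cph_energy(em, lz, cfg, gradient = FALSE)
        for (tm in names(an$terms)) {
          fd <- (Ep$terms[[tm]]$energy - Em$terms[[tm]]$energy) / (2 * h_x)
          av <- -an$terms[[tm]]$forces[i, g]
          bump(paste0(tm, "_x"),
               abs(fd - av) / max(abs(fd), abs(av), floor_))
        }
      }
    }
    for (k in seq_len(nth)) {
      lp <- lm_ <- lz
      lp[k] <- lp[k] + h_lz; lm_[k] <- lm_[k] - h_lz
      Ep <- cph_energy(sys, lp, cfg, gradient = FALSE)
      Em <- cph_energy(sys, lm_, cfg, gradient = FALSE)
      for (tm in names(an$terms)) {
        fd <- (Ep$terms[[tm]]$energy - Em$terms[[tm]]$energy) / (2 * h_lz)
        av <- an$terms[[tm]]$dlz[k]
        bump(paste0(tm, "_lz"),
             abs(fd - av) / max(abs(fd), abs(av), floor_))
      }
      # bias term via the dynamics assembly
      prm <- list(pH = 7, temperature = 298, barrier = 2)
      bp <- bias_energy(sys, lp, prm); bm <- bias_energy(sys, lm_, prm)
      ba <- bias_energy(sys, lz, prm)
      fd <- (bp$energy - bm$energy) / (2 * h_lz)
      bump("bias_lz", abs(fd - ba$dlz[k]) / max(abs(fd), abs(ba$dlz[k]),
                                                floor_))
    }
  }
  worst
}
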