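#' Simulate a fluorescence lipid-transport trace
#'
#' Single-exponential transfer kinetics with an injection offset:
#' `F(t) = F0` before `t_inject` and
#' `F(t) = F0 + (Fmax - F0) * (1 - exp(-k (t - t_inject)))` afterwards,
#' plus additive i.i.d. Gaussian noise. The slope of the noiseless signal
#' just after injection is `(Fmax - F0) * k`; expressed in delivered
#' ligand the true initial rate is `accessible_concentration(config) * k`.
#'
#' @param k transfer rate constant, 1/s (>= 0).
#' @param F0 baseline intensity, a.u.
#' @param Fmax full-transfer intensity, a.u. (> F0).
#' @param t_inject protein injection time, s.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param dt sampling interval, s (default 0.5 so eight points span 4 s).
#' @param duration trace duration, s.
#' @param seed integer seed.
#' @param config optional [assay_config()]; when given, the ground truth
#'   includes the delivered-ligand initial rate.
#' @return list with `trace` (a [kinetic_trace()] carrying `F0`, `Fmax`
#'   and the protein injection time) and `truth` (list: `k`,
#'   `true_initial_rate` in uM/s or NA without a config).
#' @export
simulate_transport_trace <- function(k, F0 = 100, Fmax = 500, t_inject = 10,
                                     noise_sd = 0, dt = 0.5, duration = 300,
                                     seed = 1, config = NULL) {
  if (k < 0) stop("k must be >= 0")
  if (Fmax <= F0) stop("Fmax must exceed F0")
  if (dt <= 0) stop("dt must be positive")
  tt <- seq(0, duration, by = dt)
  f <- ifelse(tt < t_inject, F0,
              F0 + (Fmax - F0) * (1 - exp(-k * (tt - t_inject))))
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  }
  trace <- kinetic_trace(tt, f, F0 = F0, Fmax = Fmax,
                         t_inject = c(protein = t_inject))
  truth <- list(
    k = k,
    true_initial_rate = if (is.null(config)) NA_real_ else
      accessible_concentration(config) * k)
  list(trace = trace, truth = truth)
}
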