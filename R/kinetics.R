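#' Configuration of a fluorescence lipid-transfer assay
#'
#' @param total_lipid total lipid concentration, uM.
#' @param ligand_mole_fraction mole fraction of the fluorescent/transferred
#'   ligand in `[0, 1]` (e.g. 0.05 for 5% PI4P).
#' @param accessible_fraction fraction of the ligand in the outer
#'   (protein-accessible) leaflet; default 0.5 for a large unilamellar
#'   vesicle.
#' @param protein_conc injected protein concentration, uM.
#' @param fit_points number of post-injection points in the initial-rate
#'   fit (default 8).
#' @param fit_span time window those points must span, s (default 4).
#' @return an object of class `lip_assay_config`.
#' @export
assay_config <- function(total_lipid = 200, ligand_mole_fraction = 0.05,
                         accessible_fraction = 0.5, protein_conc = 0.2,
                         fit_points = 8L, fit_span = 4) {
  if (ligand_mole_fraction < 0 || ligand_mole_fraction > 1 ||
      accessible_fraction < 0 || accessible_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (protein_conc <= 0) stop("protein_conc must be > 0")
  if (fit_points < 2L) stop("fit_points must be >= 2")
  structure(list(total_lipid = total_lipid,
                 ligand_mole_fraction = ligand_mole_fraction,
                 accessible_fraction = accessible_fraction,
                 protein_conc = protein_conc,
                 fit_points = as.integer(fit_points),
                 fit_span = fit_span),
            class = "lip_assay_config")
}

#' Accessible ligand concentration
#'
#' `total_lipid * ligand_mole_fraction * accessible_fraction`, in uM:
#' the concentration of ligand sitting in the outer leaflet and hence
#' available for extraction/transport. 200 uM lipids with 5% ligand give
#' 5 uM accessible; 80 uM with 2% give 0.8 uM.
#'
#' @param config an [assay_config()].
#' @return concentration, uM.
#' @export
accessible_concentration <- function(config) {
  config$total_lipid * config$ligand_mole_fraction *
    config$accessible_fraction
}

#' Percentage of ligand extracted from liposomes
#'
#' `100 * (1 - (F - F0)/(Fmax - F0))`: 100% when the signal falls to the
#' ligand-free baseline `F0`, 0% when it stays at the no-protein
#' reference `Fmax`. Values outside `[0, 100]` are returned as-is with a
#' `clipped` attribute flag (signal outside calibration).
#'
#' @param F measured intensity, a.u.
#' @param F0 ligand-free baseline intensity, a.u.
#' @param Fmax no-protein reference intensity, a.u.
#' @return extraction percentage (with attribute `clipped`).
#' @export
extraction_percentage <- function(F, F0, Fmax) {
  if (Fmax == F0) stop("Fmax must differ from F0")
  p <- 100 * (1 - (F - F0) / (Fmax - F0))
  out_of_range <- p < 0 | p > 100
  if (any(out_of_range)) {
    warning("extraction percentage outside [0, 100]: signal outside calibration")
  }
  attr(p, "clipped") <- out_of_range
  p
}

#' Percentage of protein bound to liposomes
#'
#' `100 * (F - Fmin)/(Fmax - Fmin)`: 0% at the buffer-only signal `Fmin`,
#' 100% at the fully-bound reference `Fmax`.
#'
#' @param F measured intensity, a.u.
#' @param Fmin buffer-only intensity, a.u.
#' @param Fmax fully-bound reference intensity, a.u.
#' @return bound percentage (with attribute `clipped`).
#' @export
bound_percentage <- function(F, Fmin, Fmax) {
  if (Fmax == Fmin) stop("Fmax must differ from Fmin")
  p <- 100 * (F - Fmin) / (Fmax - Fmin)
  out_of_range <- p < 0 | p > 100
  if (any(out_of_range)) {
    warning("bound percentage outside [0, 100]: signal outside calibration")
  }
  attr(p, "clipped") <- out_of_range
  p
}

#' Normalize a transport trace and convert it to delivered ligand
#'
#' `F_Norm(t) = (F - F0)/(Fmax - F0)` (the complement of the extraction
#' normalization) and `delivered(t) = accessible_concentration * F_Norm`,
#' in uM — e.g. 5 x F_Norm for the 200 uM / 5% / outer-leaflet transport
#' configuration.
#'
#' @param trace a [kinetic_trace()] carrying `F0` and `Fmax`.
#' @param config an [assay_config()].
#' @return data.frame with columns `time`, `F`, `f_norm`, `delivered_uM`.
#' @export
normalize_transport <- function(trace, config) {
  cal <- trace_calibration(trace)
  if (is.na(cal$F0) || is.na(cal$Fmax)) {
    stop("trace calibration must provide F0 and Fmax")
  }
  if (cal$Fmax == cal$F0) stop("Fmax must differ from F0")
  f_norm <- (trace$F - cal$F0) / (cal$Fmax - cal$F0)
  data.frame(time = trace$time, F = trace$F, f_norm = f_norm,
             delivered_uM = accessible_concentration(config) * f_norm)
}

#' Initial transport rate from a normalized trace
#'
#' Ordinary least-squares fit (intercept free, so an injection artifact
#' in the first point does not bias the slope) of delivered ligand
#' against time over the first `fit_points` samples strictly after the
#' protein injection; those points must span no more than `fit_span`
#' seconds (default: eight points over 4 s). The per-protein rate is
#' `slope * 60 / protein_conc`, in lipids per minute per protein.
#'
#' @param trace a [kinetic_trace()].
#' @param config an [assay_config()].
#' @param t_protein protein injection time, s; default: the trace's
#'   injection named "protein".
#' @return list (class `lip_rate_result`) with `initial_rate_uM_s`,
#'   `per_protein_rate_min`, `slope_se`, `r_squared`, `n_points`,
#'   `fit_window_s`.
#' @export
initial_rate <- function(trace, config, t_protein = NULL) {
  if (is.null(t_protein)) {
    inj <- trace_calibration(trace)$t_inject
    t_protein <- inj[["protein"]]
  }
  norm <- normalize_transport(trace, config)
  post <- which(norm$time > t_protein)
  if (length(post) < config$fit_points) {
    stop("insufficient post-injection samples: need ", config$fit_points,
         ", have ", length(post))
  }
  sel <- post[seq_len(config$fit_points)]
  tspan <- norm$time[sel[config$fit_points]] - norm$time[sel[1]]
  if (tspan > config$fit_span + 1e-9) {
    stop("the first ", config$fit_points, " post-injection points span ",
         format(tspan, digits = 3), " s > fit_span = ", config$fit_span, " s")
  }
  fit <- stats::lm(delivered_uM ~ time, data = norm[sel, ])
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  structure(list(
    initial_rate_uM_s = slope,
    per_protein_rate_min = slope * 60 / config$protein_conc,
    slope_se = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n_points = config$fit_points,
    fit_window_s = c(norm$time[sel[1]], norm$time[sel[config$fit_points]])),
    class = "lip_rate_result")
}

#' @export
print.lip_rate_result <- function(x, ...) {
  cat("<lip_rate_result> initial rate ",
      format(x$initial_rate_uM_s, digits = 4), " uM/s (",
      format(x$per_protein_rate_min, digits = 4),
      " lipids/min/protein), R^2 = ", format(x$r_squared, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Fit the transfer rate constant of an exponential trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `F0 + (Fmax - F0) * (1 - exp(-k (t - t_inject)))` to the
#' post-injection segment. By default the calibration anchors `F0` and
#' `Fmax` are held fixed and only `k` is fitted; `fit_anchors = TRUE`
#' frees all three.
#'
#' @param trace a [kinetic_trace()] carrying `F0` and `Fmax`.
#' @param t_inject injection time, s; default: the trace's "protein"
#'   injection.
#' @param fit_anchors also fit F0 and Fmax (default FALSE).
#' @return list with `k` (1/s), `k_se`, and the `fit` object.
#' @export
fit_transfer_k <- function(trace, t_inject = NULL, fit_anchors = FALSE) {
  cal <- trace_calibration(trace)
  if (is.null(t_inject)) t_inject <- cal$t_inject[["protein"]]
  post <- trace$time > t_inject
  if (sum(post) < 3L) stop("too few post-injection samples to fit")
  dat <- data.frame(t = trace$time[post] - t_inject, y = trace$F[post])
  if (is.na(cal$F0) || is.na(cal$Fmax)) {
    stop("trace calibration must provide F0 and Fmax")
  }
  amp <- cal$Fmax - cal$F0
  # crude slope-based start; k = initial slope / amplitude
  n0 <- min(5L, nrow(dat))
  k0 <- max(1e-4, unname(stats::coef(stats::lm(y ~ t, dat[seq_len(n0), ]))[2]) / amp)
  fit <- tryCatch(
    if (fit_anchors) {
      minpack.lm::nlsLM(y ~ f0 + (fmax - f0) * (1 - exp(-k * t)), data = dat,
                        start = list(k = k0, f0 = cal$F0, fmax = cal$Fmax))
    } else {
      dat$baseline <- cal$F0
      dat$amplitude <- amp
      minpack.lm::nlsLM(y ~ baseline + amplitude * (1 - exp(-k * t)),
                        data = dat, start = list(k = k0), lower = 0)
    },
    error = function(e) stop("rate-constant fit failed to converge: ",
                             conditionMessage(e)))
  est <- summary(fit)$coefficients
  list(k = est["k", "Estimate"], k_se = est["k", "Std. Error"], fit = fit)
}

#' Min-max normalization of a dissociation trace
#'
#' Real-time dissociation traces are reported on a relative scale; with
#' no calibration stated beyond "normalized", the signal is mapped
#' linearly so its minimum is 0 and maximum is 1 (flagged as a
#' convention, not a calibrated quantity).
#'
#' @param trace a [kinetic_trace()].
#' @return data.frame with columns `time` and `f_norm`.
#' @export
normalize_dissociation <- function(trace) {
  rng <- range(trace$F)
  if (diff(rng) == 0) stop("flat trace cannot be min-max normalized")
  data.frame(time = trace$time, f_norm = (trace$F - rng[1]) / diff(rng))
}
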