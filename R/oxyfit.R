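#' Hill oxygen-saturation function
#'
#' Fractional saturation of hemoglobin at a given oxygen tension under the
#' Hill model, `Y = PO2^n / (P50^n + PO2^n)`. `P50` is the tension (torr) at
#' half-saturation; `n` is the cooperativity coefficient.
#'
#' Computed on the log scale via `plogis(n * (log(po2) - log(p50)))` so that
#' large `po2^n` cannot overflow.
#'
#' @param po2 oxygen partial pressure(s), torr; `>= 0`.
#' @param p50 half-saturation pressure, torr; `> 0`.
#' @param n Hill cooperativity coefficient; `> 0`.
#' @return Fractional saturation(s) in `[0, 1]`.
#' @examples
#' hill_saturation(3.42, p50 = 3.42, n = 2.3)  # exactly 0.5
#' @export
hill_saturation <- function(po2, p50, n) {
  if (!is.numeric(p50) || length(p50) != 1L || !is.finite(p50) || p50 <= 0)
    stop_hb("invalid_parameter", "p50 must be a single positive number")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop_hb("invalid_parameter", "n must be a single positive number")
  if (any(po2 < 0))
    stop_hb("invalid_parameter", "po2 must be non-negative")
  out <- ifelse(po2 == 0, 0, stats::plogis(n * (log(po2) - log(p50))))
  as.numeric(out)
}

#' Construct an effector treatment descriptor
#'
#' Treatments are the standardized assay conditions under which O2 equilibria
#' are measured: `stripped` (no allosteric effectors), `KCl` (chloride),
#' `IHP` (inositol hexaphosphate) or `KCl+IHP`.
#'
#' @param label one of `"stripped"`, `"KCl"`, `"IHP"`, `"KCl+IHP"`.
#' @param kcl_molar KCl concentration (M); must be absent for `stripped`.
#' @param ihp_ratio IHP : Hb-tetramer molar ratio; must be absent for `stripped`.
#' @param ph buffer pH.
#' @param temperature_c assay temperature, degrees C.
#' @param heme_mM heme concentration, mM.
#' @return A list of class `"hb_treatment"`.
#' @export
hb_treatment <- function(label = c("stripped", "KCl", "IHP", "KCl+IHP"),
                         kcl_molar = NULL, ihp_ratio = NULL,
                         ph = 7.4, temperature_c = 37, heme_mM = 0.3) {
  label <- match.arg(label)
  if (label == "stripped" && (!is.null(kcl_molar) || !is.null(ihp_ratio)))
    stop_hb("invalid_parameter", "stripped treatment cannot carry effector concentrations")
  if (label %in% c("KCl", "KCl+IHP") && is.null(kcl_molar)) kcl_molar <- 0.1
  if (label %in% c("IHP", "KCl+IHP") && is.null(ihp_ratio)) ihp_ratio <- 2
  stopifnot(is.numeric(ph), is.numeric(temperature_c))
  structure(list(label = label, kcl_molar = kcl_molar, ihp_ratio = ihp_ratio,
                 ph = ph, temperature_c = temperature_c, heme_mM = heme_mM),
            class = "hb_treatment")
}

#' Construct an O2 saturation curve
#'
#' One replicate equilibrium curve: fractional saturation measured at a series
#' of stepwise oxygen tensions (5-8 equilibration steps in the diffusion
#' chamber protocol this models).
#'
#' @param po2_torr strictly increasing positive oxygen tensions, torr.
#' @param saturation fractional saturations; values in `[0, 1]` up to a small
#'   noise allowance (measurement noise may nudge points just outside).
#' @param genotype genotype code the sample carries (string).
#' @param treatment an [hb_treatment()] or treatment label.
#' @param replicate_id replicate identifier.
#' @return A list of class `"saturation_curve"`.
#' @export
saturation_curve <- function(po2_torr, saturation, genotype = NA_character_,
                             treatment = "stripped", replicate_id = 1L) {
  if (length(po2_torr) != length(saturation))
    stop_hb("invalid_parameter", "po2_torr and saturation lengths differ")
  if (length(po2_torr) < 3L)
    stop_hb("insufficient_data", "a saturation curve needs at least 3 points, got ",
            length(po2_torr))
  if (any(!is.finite(po2_torr)) || any(po2_torr <= 0))
    stop_hb("invalid_parameter", "po2 values must be finite and strictly positive")
  if (any(diff(po2_torr) <= 0))
    stop_hb("invalid_parameter", "po2 values must be strictly increasing")
  if (any(!is.finite(saturation)) ||
      any(saturation < -0.05) || any(saturation > 1.05))
    stop_hb("invalid_parameter", "saturations must lie in [0, 1] up to noise tolerance")
  if (is.character(treatment)) treatment <- hb_treatment(treatment)
  structure(list(po2_torr = as.numeric(po2_torr),
                 saturation = as.numeric(saturation),
                 genotype = genotype, treatment = treatment,
                 replicate_id = replicate_id),
            class = "saturation_curve")
}

## deterministic Hill-plot initialization: logit(Y) regressed on log(PO2)
## over points with 0.05 < Y < 0.95; slope = n, x-intercept = log(P50)
hill_init <- function(po2, sat) {
  keep <- sat > 0.05 & sat < 0.95
  if (sum(keep) >= 2L) {
    x <- log(po2[keep])
    y <- stats::qlogis(pmin(pmax(sat[keep], 1e-9), 1 - 1e-9))
    co <- stats::coef(stats::lm(y ~ x))
    n0 <- unname(co[2L])
    if (is.finite(n0) && n0 > 0) {
      p0 <- exp(-unname(co[1L]) / n0)
      if (is.finite(p0) && p0 > 0) return(list(p50 = p0, n = n0))
    }
  }
  ## fallback: PO2 nearest half-saturation, mild cooperativity
  list(p50 = po2[which.min(abs(sat - 0.5))], n = 2)
}

#' Fit the Hill equation to a saturation curve
#'
#' Unweighted nonlinear least squares of `Y = PO2^n / (P50^n + PO2^n)` on the
#' observed saturations. Initialization, unless supplied, comes from a Hill
#' plot (logit-log) linearization, which is deterministic. `converged` is
#' `TRUE` only when the optimizer reports success and the fitted P50 lies
#' within the observed PO2 range extended one decade on each side; otherwise
#' the fit is still returned, flagged, never silently dropped.
#'
#' @param curve a [saturation_curve()].
#' @param init optional list/vector with elements `p50` and `n`.
#' @param weights optional per-point weights (off by default; unweighted
#'   least squares is the reference behaviour).
#' @return An object of class `"hill_fit"`: `p50_torr`, `n50`, `p50_se`,
#'   `n50_se` (asymptotic fit SEs), `r_squared`, `converged`, plus the inputs.
#' @examples
#' po2 <- exp(seq(log(0.5), log(30), length.out = 8))
#' cv <- saturation_curve(po2, hill_saturation(po2, 4.3, 2.5))
#' fit_hill(cv)
#' @export
fit_hill <- function(curve, init = NULL, weights = NULL) {
  stopifnot(inherits(curve, "saturation_curve"))
  po2 <- curve$po2_torr
  sat <- curve$saturation
  if (length(unique(sat)) == 1L)
    stop_hb("degenerate_curve", "all saturations identical; curve carries no shape")
  if (is.null(init)) init <- hill_init(po2, sat)
  init <- list(p50 = as.numeric(init[["p50"]]), n = as.numeric(init[["n"]]))
  if (init$p50 <= 0 || init$n <= 0)
    stop_hb("invalid_parameter", "initial p50 and n must be positive")

  df <- data.frame(po2 = po2, sat = sat)
  ctrl <- stats::nls.control(maxiter = 10000L, tol = 1e-8, minFactor = 1e-12,
                             scaleOffset = 1, warnOnly = FALSE)
  fit <- tryCatch(
    stats::nls(sat ~ stats::plogis(n * (log(po2) - log(p50))), data = df,
               start = init, weights = weights, control = ctrl),
    error = function(e) e)
  ok <- !inherits(fit, "error")
  if (ok) {
    est <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
      c(p50 = NA_real_, n = NA_real_))
    pred <- stats::fitted(fit)
  } else {
    est <- c(p50 = init$p50, n = init$n)
    se <- c(p50 = NA_real_, n = NA_real_)
    pred <- hill_saturation(po2, est[["p50"]], est[["n"]])
  }
  ss_res <- sum((sat - pred)^2)
  ss_tot <- sum((sat - mean(sat))^2)
  p50 <- unname(est[["p50"]])
  in_range <- p50 >= min(po2) / 10 && p50 <= max(po2) * 10
  structure(list(p50_torr = p50, n50 = unname(est[["n"]]),
                 p50_se = unname(se[["p50"]]), n50_se = unname(se[["n"]]),
                 r_squared = 1 - ss_res / ss_tot,
                 converged = ok && in_range,
                 genotype = curve$genotype,
                 treatment = curve$treatment$label,
                 replicate_id = curve$replicate_id,
                 n_points = length(po2)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: P50 = %.4g torr (SE %.3g), n50 = %.4g (SE %.3g), R2 = %.5f%s\n",
              x$p50_torr, x$p50_se, x$n50, x$n50_se, x$r_squared,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarize replicate fits
#'
#' Mean, standard error of the mean, and count over the converged fits of a
#' replicate series (triplicates in the reference protocol). The SEM is the
#' sample standard deviation divided by `sqrt(n)`; it is `NA` for a single
#' fit, where between-replicate scatter is undefined.
#'
#' @param fits list of [fit_hill()] results (or numeric values via `value`).
#' @param value which component to summarize, default `"p50_torr"`.
#' @return list with `mean`, `sem`, `n`, and `mean_fit_se` (mean asymptotic
#'   per-fit SE, reported separately from replicate scatter).
#' @export
summarize_replicates <- function(fits, value = "p50_torr") {
  if (inherits(fits, "hill_fit")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L)
    stop_hb("no_data", "no converged fits to summarize")
  x <- vapply(conv, function(f) f[[value]], numeric(1))
  fit_se <- vapply(conv, function(f) {
    se_name <- if (value == "n50") "n50_se" else "p50_se"
    if (is.null(f[[se_name]])) NA_real_ else f[[se_name]]
  }, numeric(1))
  n <- length(x)
  list(mean = mean(x),
       sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
       n = n,
       mean_fit_se = mean(fit_se))
}

#' Anion-sensitivity index
#'
#' Sensitivity of Hb-O2 affinity to an allosteric effector, indexed as the
#' difference in log10-transformed P50 with and without the effector:
#' `delta log P50 = log10(P50_effector) - log10(P50_stripped)`. Higher values
#' mean stronger affinity reduction by the anion.
#'
#' @param p50_stripped,p50_effector P50 (torr) without / with the effector;
#'   both `> 0`.
#' @param treatment_pair optional labels for the two conditions.
#' @return list of class `"anion_sensitivity"` with `delta_log_p50` and
#'   `treatment_pair`.
#' @examples
#' anion_sensitivity(4.30, 4.30 * 10^0.630)$delta_log_p50  # 0.630
#' @export
anion_sensitivity <- function(p50_stripped, p50_effector,
                              treatment_pair = c("stripped", "effector")) {
  if (!is.finite(p50_stripped) || p50_stripped <= 0 ||
      !is.finite(p50_effector) || p50_effector <= 0)
    stop_hb("invalid_parameter", "both P50 values must be finite and positive")
  structure(list(delta_log_p50 = log10(p50_effector) - log10(p50_stripped),
                 treatment_pair = treatment_pair),
            class = "anion_sensitivity")
}
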