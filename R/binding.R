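# Fluorescence-polarization binding models: quadratic direct-binding
# saturation and sigmoidal dose-response competition.

#' Quadratic direct-binding value
#'
#' Evaluates the closed-form bound-fraction signal at titrated protein
#' concentration X for a fixed probe concentration:
#' `Y = A (pept + X + KD - sqrt((pept + X + KD)^2 - 4 pept X)) / 2 + B`.
#' A numerically negative discriminant is clamped to 0 with a warning.
#'
#' @param X protein concentration(s), >= 0 (same units as `pept` and `KD`).
#' @param pept fixed probe peptide concentration (> 0).
#' @param KD dissociation constant (>= 0).
#' @param A signal amplitude per unit probe concentration.
#' @param B baseline plateau.
#' @return numeric signal value(s).
#' @export
direct_binding_value <- function(X, pept, KD, A, B) {
  stopifnot(all(X >= 0), pept > 0, KD >= 0)
  s <- pept + X + KD
  disc <- s^2 - 4 * pept * X
  if (any(disc < 0)) {
    warning("negative discriminant clamped to 0")
    disc <- pmax(disc, 0)
  }
  A * (s - sqrt(disc)) / 2 + B
}

#' Fit the quadratic direct-binding model
#'
#' Unweighted nonlinear least squares of [direct_binding_value()] to a
#' saturation titration, returning KD, A and B with standard errors.  A flat
#' titration (amplitude indistinguishable from zero) is flagged: KD is then
#' unidentifiable.
#'
#' @param X,Y titration points (>= 5, spanning the transition).
#' @param pept fixed probe concentration.
#' @return list of class `fp_fit` with KD, A, B, their standard errors,
#'   converged and flat flags, and the `nls` object.
#' @export
fit_direct <- function(X, Y, pept) {
  stopifnot(length(X) == length(Y), length(X) >= 5L)
  d <- data.frame(X = X, Y = Y)
  amp0 <- max(Y) - min(Y)
  starts <- expand.grid(
    KD = unique(pmax(c(quantile(X[X > 0], c(0.25, 0.5, 0.75)), pept),
                     .Machine$double.eps)),
    A = c(amp0 / pept, 2 * amp0 / pept))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Y ~ direct_binding_value(X, pept, KD, A, B), data = d,
        start = list(KD = starts$KD[i], A = starts$A[i], B = min(Y)),
        lower = c(0, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(KD = NA_real_, A = NA_real_, B = NA_real_,
                          se = c(KD = NA_real_, A = NA_real_, B = NA_real_),
                          converged = FALSE, flat = NA, fit = NULL),
                     class = "fp_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))),
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  flat <- abs(cf[["A"]] * pept) < 2 * sd(Y)
  structure(list(KD = unname(cf[["KD"]]), A = unname(cf[["A"]]),
                 B = unname(cf[["B"]]), se = se, converged = TRUE,
                 flat = flat, fit = best$fit),
            class = "fp_fit")
}

# Four-parameter logistic on log10 concentration.
four_pl <- function(logX, bottom, top, logIC50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (logX - logIC50)))
}

#' Fit a sigmoidal dose-response competition curve
#'
#' Four-parameter logistic fit on log10 competitor concentration
#' (bottom, top, IC50, slope), as used for FP displacement experiments.
#' Data showing no displacement (slope indistinguishable from zero, or
#' signal rising with competitor) are flagged.
#'
#' @param conc competitor concentrations (> 0).
#' @param Y polarization signal.
#' @return list of class `fp_competition_fit` with bottom, top, IC50,
#'   slope, standard errors, converged and no_displacement flags.
#' @export
fit_competition <- function(conc, Y) {
  stopifnot(length(conc) == length(Y), length(conc) >= 5L, all(conc > 0))
  d <- data.frame(logX = log10(conc), Y = Y)
  best <- NULL
  for (lic in quantile(d$logX, c(0.25, 0.5, 0.75))) {
    for (sl in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          Y ~ four_pl(logX, bottom, top, logIC50, slope), data = d,
          start = list(bottom = min(Y), top = max(Y), logIC50 = lic,
                       slope = sl),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, IC50 = NA_real_,
                          slope = NA_real_, se = NULL, converged = FALSE,
                          no_displacement = NA),
                     class = "fp_competition_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))),
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  slope_se <- se[["slope"]]
  no_disp <- (!is.na(slope_se) && abs(cf[["slope"]]) < 2 * slope_se) ||
    cf[["top"]] < cf[["bottom"]]
  structure(list(bottom = min(cf[["bottom"]], cf[["top"]]),
                 top = max(cf[["bottom"]], cf[["top"]]),
                 IC50 = 10^cf[["logIC50"]], slope = unname(cf[["slope"]]),
                 se = se, converged = TRUE, no_displacement = no_disp,
                 fit = best$fit),
            class = "fp_competition_fit")
}

#' Convert a competition IC50 to an inhibition constant
#'
#' Optional Cheng-Prusoff-style conversion
#' `KI = IC50 / (1 + [probe] / KD_probe)`; provided as a documented
#' convenience, not part of the core fitting.
#'
#' @param IC50 fitted midpoint.
#' @param probe_conc probe peptide concentration.
#' @param KD_probe probe dissociation constant from [fit_direct()].
#' @return KI estimate.
#' @export
ic50_to_ki <- function(IC50, probe_conc, KD_probe) {
  IC50 / (1 + probe_conc / KD_probe)
}
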