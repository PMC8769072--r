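# Library coverage statistics and two-hyperbola saturation extrapolation.

#' Sequenced coverage of a library design
#'
#' @param observed character vector of observed peptide (or oligo)
#'   sequences.
#' @param design character vector of designed sequences (non-empty).
#' @return fraction of the design observed; sequences outside the design are
#'   ignored.
#' @export
sequenced_coverage <- function(observed, design) {
  if (!length(design)) stop("empty design")
  length(intersect(unique(observed), unique(design))) / length(unique(design))
}

#' Accumulation curves over sequenced aliquots
#'
#' For each of `n_shuffles` random orderings of the aliquots, appends them
#' cumulatively and records the cumulative unique design-matching sequences
#' (as percent of the design) against the cumulative reads contributed.
#'
#' @param aliquots list; each element a list with `peptides` (character) and
#'   `reads` (total read count of the aliquot).
#' @param design character vector of designed sequences.
#' @param n_shuffles number of random orderings (10).
#' @param seed integer seed.
#' @return data.frame with shuffle, step, X (cumulative reads), Y (percent
#'   of design observed).
#' @export
accumulation_curves <- function(aliquots, design, n_shuffles = 10L, seed = 1L) {
  stopifnot(length(aliquots) >= 2L)
  set.seed(seed)
  design <- unique(design)
  rows <- list()
  for (s in seq_len(n_shuffles)) {
    ord <- sample(seq_along(aliquots))
    seen <- character(0)
    X <- 0
    for (step in seq_along(ord)) {
      al <- aliquots[[ord[step]]]
      seen <- union(seen, intersect(al$peptides, design))
      X <- X + al$reads
      rows[[length(rows) + 1L]] <- data.frame(
        shuffle = s, step = step, X = X,
        Y = 100 * length(seen) / length(design))
    }
  }
  do.call(rbind, rows)
}

# Two-hyperbola saturation model.
two_hyperbola <- function(X, Ymax1, a, Ymax2, b) {
  Ymax1 * X / (a + X) + Ymax2 * X / (b + X)
}

#' Fit the two-hyperbola coverage model
#'
#' Nonlinear least squares of `Y = Ymax1 X/(a+X) + Ymax2 X/(b+X)` with
#' multiple starts (plateau splits for the asymptotes, log-spaced
#' half-saturation constants).  The predicted maximum coverage is
#' `Ymax1 + Ymax2`, with its standard error propagated from the parameter
#' covariance (`var = V11 + V22 + 2 V12`).  Components are canonicalized to
#' `a <= b`.
#'
#' @param curve data.frame with columns X and Y (>= 6 points).
#' @return list of class `coverage_fit` with parameters, predicted_max,
#'   predicted_max_se, converged, and the `nls` fit object.
#' @export
fit_coverage <- function(curve) {
  curve <- curve[order(curve$X), , drop = FALSE]
  if (nrow(curve) < 6L) stop("need at least 6 points")
  plateau <- max(curve$Y)
  if (plateau <= 0) {
    return(structure(list(Ymax1 = 0, a = NA_real_, Ymax2 = 0, b = NA_real_,
                          predicted_max = 0, predicted_max_se = 0,
                          converged = TRUE, fit = NULL),
                     class = "coverage_fit"))
  }
  xr <- range(curve$X[curve$X > 0])
  grid_ab <- 10^seq(log10(xr[1] / 10), log10(xr[2] * 10), length.out = 4)
  best <- NULL
  for (split in c(0.5, 0.7, 0.9)) {
    for (a0 in grid_ab) for (b0 in grid_ab) {
      if (b0 < a0) next
      fit <- tryCatch(
        minpack.lm::nlsLM(
          Y ~ two_hyperbola(X, Ymax1, a, Ymax2, b), data = curve,
          start = list(Ymax1 = split * plateau, a = a0,
                       Ymax2 = (1 - split) * plateau, b = b0),
          lower = c(0, 0, 0, 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(Ymax1 = NA_real_, a = NA_real_, Ymax2 = NA_real_,
                          b = NA_real_, predicted_max = NA_real_,
                          predicted_max_se = NA_real_, converged = FALSE,
                          fit = NULL),
                     class = "coverage_fit"))
  }
  cf <- coef(best$fit)
  V <- tryCatch(vcov(best$fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  if (cf[["a"]] > cf[["b"]]) {  # canonicalize exchangeable components
    cf <- cf[c("Ymax2", "b", "Ymax1", "a")]
    names(cf) <- c("Ymax1", "a", "Ymax2", "b")
    V <- V[c("Ymax2", "b", "Ymax1", "a"), c("Ymax2", "b", "Ymax1", "a")]
  }
  var_sum <- V["Ymax1", "Ymax1"] + V["Ymax2", "Ymax2"] +
    2 * V["Ymax1", "Ymax2"]
  structure(list(Ymax1 = unname(cf[["Ymax1"]]), a = unname(cf[["a"]]),
                 Ymax2 = unname(cf[["Ymax2"]]), b = unname(cf[["b"]]),
                 predicted_max = unname(cf[["Ymax1"]] + cf[["Ymax2"]]),
                 predicted_max_se = sqrt(max(var_sum, 0)),
                 converged = TRUE, fit = best$fit),
            class = "coverage_fit")
}

#' @export
print.coverage_fit <- function(x, ...) {
  cat(sprintf(
    "<coverage_fit> predicted max %.2f%% +/- %.2f (Ymax1 %.2f @ a=%.3g, Ymax2 %.2f @ b=%.3g)\n",
    x$predicted_max, x$predicted_max_se, x$Ymax1, x$a, x$Ymax2, x$b))
  invisible(x)
}
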