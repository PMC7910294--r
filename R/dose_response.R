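#' Four-parameter logistic curve
#'
#' Constructs the increasing four-parameter logistic (4PL)
#' \deqn{f(x) = bottom + \frac{top - bottom}{1 + (ec50/x)^{hill}}}
#' used both to calibrate the stimulus concentration-response (EC50 of the
#' IL-1beta induction) and as the immunoassay standard curve. By
#' construction `f(ec50) = (top + bottom) / 2` and `f(0) = bottom`.
#'
#' Inhibition is represented downstream as activity ratios, never as a
#' descending curve, so `hill > 0` and `top > bottom` always.
#'
#' @param bottom Lower asymptote, response units.
#' @param top Upper asymptote, response units; must exceed `bottom`.
#' @param ec50 Concentration of half-maximal response; > 0.
#' @param hill Hill slope; > 0.
#' @return An object of class `fourpl`.
#' @export
fourpl <- function(bottom, top, ec50, hill) {
  if (!is.finite(bottom) || !is.finite(top) || top <= bottom) {
    abort("fourpl requires finite top > bottom",
          class = "screenfunnel_curve_error")
  }
  if (!is.finite(ec50) || ec50 <= 0 || !is.finite(hill) || hill <= 0) {
    abort("fourpl requires ec50 > 0 and hill > 0",
          class = "screenfunnel_curve_error")
  }
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill),
            class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  cat(sprintf("<fourpl> bottom=%.6g top=%.6g ec50=%.6g hill=%.4g\n",
              x$bottom, x$top, x$ec50, x$hill))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' @param object A `fourpl` curve.
#' @param x Concentrations (>= 0); `x = 0` returns `bottom` (the limit of
#'   the curve, and the zero-concentration standard point).
#' @param ... Unused.
#' @return Responses at `x`.
#' @export
predict.fourpl <- function(object, x, ...) {
  y <- object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50 / x)^object$hill)
  y[x == 0] <- object$bottom
  y
}

#' Invert a 4PL curve
#'
#' Back-calculates the concentration producing response `y`:
#' `x = ec50 * ((top - bottom)/(y - bottom) - 1)^(-1/hill)`. Used to
#' convert immunoassay fluorescence to concentration against a standard
#' curve. In batch use, readings at or below `bottom` are below the
#' detection limit and readings at or above `top` are above range; with
#' `flag = TRUE` these return `NA` with a detection label instead of
#' erroring.
#'
#' @param curve A `fourpl` curve.
#' @param y Response value(s).
#' @param flag If `TRUE`, return a tibble with columns `concentration` and
#'   `detection` (`ok`, `below_lod`, `above_range`) instead of erroring on
#'   out-of-range input.
#' @return Concentration(s), or a tibble when `flag = TRUE`.
#' @export
inverse_4pl <- function(curve, y, flag = FALSE) {
  stopifnot(inherits(curve, "fourpl"))
  below <- y <= curve$bottom
  above <- y >= curve$top
  x <- rep(NA_real_, length(y))
  ok <- !below & !above
  x[ok] <- curve$ec50 *
    ((curve$top - curve$bottom) / (y[ok] - curve$bottom) - 1)^(-1 / curve$hill)
  if (flag) {
    detection <- ifelse(below, "below_lod", ifelse(above, "above_range", "ok"))
    return(tibble::tibble(concentration = x, detection = detection))
  }
  if (any(below)) {
    abort("response at or below curve bottom: below detection",
          class = "screenfunnel_below_detection")
  }
  if (any(above)) {
    abort("response at or above curve top: above range",
          class = "screenfunnel_above_range")
  }
  x
}

# response with the zero-dose point anchored at bottom, used inside nls
fourpl_fn <- function(x, bottom, top, lec50, hill) {
  y <- bottom + (top - bottom) / (1 + exp(hill * (lec50 - log(x))))
  y[x == 0] <- bottom
  y
}

#' Fit a four-parameter logistic curve
#'
#' Nonlinear least squares on log-dose. Initialization: asymptotes from the
#' response extremes, EC50 from the dose bracketing the half-range
#' crossing, Hill slope 1. A zero-concentration point (the 0 pg/mL standard
#' of an 11-point immunoassay curve) is kept out of the log transform and
#' anchors the bottom asymptote.
#'
#' @param doses Concentrations (>= 0; at least 5 distinct positive values).
#' @param responses Responses, same length, finite.
#' @param tol Relative response range below which the data are considered
#'   flat and unfittable.
#' @return A list with elements `curve` (a [fourpl()]), `residuals`,
#'   `rss`, and `converged`.
#' @export
fit_4pl <- function(doses, responses, tol = 1e-8) {
  if (length(doses) != length(responses)) {
    abort("doses and responses must have equal length")
  }
  keep <- is.finite(doses) & is.finite(responses) & doses >= 0
  if (!all(keep)) abort("doses must be >= 0 and responses finite")
  if (length(unique(doses[doses > 0])) < 5) {
    abort("need at least 5 distinct positive doses",
          class = "screenfunnel_fit_error")
  }
  rng <- range(responses)
  if (diff(rng) < tol * max(abs(rng), 1)) {
    abort("responses are flat: degenerate curve",
          class = "screenfunnel_degenerate_curve")
  }

  o <- order(doses)
  d <- doses[o]; y <- responses[o]
  bottom0 <- min(y); top0 <- max(y)
  half <- (bottom0 + top0) / 2
  pos <- d > 0
  cross <- which(y[pos] >= half)
  lec50_0 <- if (length(cross) > 0 && cross[1] > 1) {
    mean(log(d[pos][c(cross[1] - 1, cross[1])]))
  } else {
    median(log(d[pos]))
  }

  dat <- data.frame(x = d, y = y)
  fit <- tryCatch(
    stats::nls(
      y ~ fourpl_fn(x, bottom, top, lec50, hill),
      data = dat,
      start = list(bottom = bottom0, top = top0, lec50 = lec50_0, hill = 1),
      # scaleOffset makes the convergence test sound on zero-residual
      # (noiseless) data, where the plain relative-offset criterion fails
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                   minFactor = 1e-10, scaleOffset = 1, tol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # retry with a softer criterion before giving up
    fit <- tryCatch(
      suppressWarnings(stats::nls(
        y ~ fourpl_fn(x, bottom, top, lec50, hill),
        data = dat,
        start = list(bottom = bottom0, top = top0, lec50 = lec50_0, hill = 1),
        control = stats::nls.control(maxiter = 500, warnOnly = TRUE,
                                     minFactor = 1e-12, scaleOffset = 1, tol = 1e-10))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      abort(paste0("4PL fit failed to converge: ", conditionMessage(fit)),
            class = "screenfunnel_fit_error")
    }
  }
  cf <- stats::coef(fit)
  if (cf[["top"]] < cf[["bottom"]]) {
    # canonicalise a mirrored solution (nls is free to swap asymptotes)
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf[["hill"]] <- -cf[["hill"]]
  }
  curve <- fourpl(bottom = cf[["bottom"]], top = cf[["top"]],
                  ec50 = exp(cf[["lec50"]]), hill = cf[["hill"]])
  list(curve = curve,
       residuals = as.numeric(stats::resid(fit)),
       rss = sum(stats::resid(fit)^2),
       converged = isTRUE(fit$convInfo$isConv))
}

#' Choose a submaximal stimulation concentration
#'
#' Returns the lowest candidate dose whose fractional response
#' `(f(x) - bottom)/(top - bottom)` is at least `min_fraction` on every
#' channel's fitted curve. A working point near the half-maximum leaves
#' headroom in both directions, so the screen can detect compounds that
#' either induce or attenuate the response. With the calibrated EC50s of
#' 0.02 (CCL2) and 0.03 ng/mL (ICAM-1) and candidates 0.01/0.05/0.5 ng/mL
#' this selects 0.05 ng/mL.
#'
#' @param curves A named list of `fourpl` curves, one per channel.
#' @param candidate_doses Positive candidate concentrations.
#' @param min_fraction Minimum fractional response on every channel
#'   (inclusive); default 0.5.
#' @return A list with `dose` (the chosen dose) and `fractions` (a tibble
#'   of fractional responses per candidate and channel).
#' @export
pick_stimulation_dose <- function(curves, candidate_doses,
                                  min_fraction = 0.5) {
  if (inherits(curves, "fourpl")) curves <- list(channel = curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "fourpl")))
  if (length(candidate_doses) == 0 || any(candidate_doses <= 0)) {
    abort("candidate doses must be positive")
  }
  doses <- sort(unique(candidate_doses))
  frac <- lapply(curves, function(cv) {
    (predict(cv, doses) - cv$bottom) / (cv$top - cv$bottom)
  })
  tab <- tibble::tibble(dose = doses)
  for (ch in names(frac)) tab[[ch]] <- frac[[ch]]
  min_frac <- apply(as.matrix(tab[, -1, drop = FALSE]), 1, min)
  ok <- min_frac >= min_fraction
  if (!any(ok)) {
    abort(paste0("no candidate dose reaches fraction ", min_fraction,
                 " on every channel; best fractions: ",
                 paste(sprintf("%g: %.3f", doses, min_frac), collapse = ", ")),
          class = "screenfunnel_dose_error")
  }
  list(dose = doses[which(ok)[1]], fractions = tab)
}
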