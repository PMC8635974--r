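## Hill concentration-response and competition-binding fits. All
## concentration fitting is done in log10 space with untransformed
## responses; positivity of EC50/IC50 and of the slope comes from the
## parameterization (log10 EC50 free, log slope free).

hill_curve <- function(conc, ec50, top, hill, bottom = 0) {
  out <- bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
  out[conc == 0] <- bottom
  out
}

#' Fit the Hill equation with variable slope and bottom fixed at zero
#'
#' `Y = top * [A]^h / ([A]^h + EC50^h)`. Fitted by least squares over
#' (log10 EC50, top, log h); the bottom is fixed at 0 by convention (the
#' responses are baseline-subtracted fractions of a reference response).
#'
#' @param conc agonist concentrations (mol/L); zeros allowed.
#' @param response responses.
#' @param top fix the top at this value, or NULL (default) to fit it.
#' @param bottom fixed bottom (default 0).
#' @return object of class `hill_fit`: `ec50`, `top`, `bottom`,
#'   `hill_slope`, `sse`, `vcov` (on log10 EC50, top if free, log h),
#'   `converged`, `flags`.
#' @export
fit_hill <- function(conc, response, top = NULL, bottom = 0) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct concentrations")
  flags <- character(0)
  rng <- range(response)
  if (diff(rng) < 1e-3 * max(abs(rng), 1))
    flags <- c(flags, "non_convergent")  # no transition in range
  top_free <- is.null(top)
  lc_mid <- log10(stats::median(conc[conc > 0]))
  predict_par <- function(p) {
    ec50 <- 10^p[1]
    tp <- if (top_free) p[2] else top
    h <- exp(p[if (top_free) 3 else 2])
    hill_curve(conc, ec50, tp, h, bottom)
  }
  obj <- function(p) sum((predict_par(p) - response)^2)
  start <- if (top_free) c(lc_mid, max(response), 0) else c(lc_mid, 0)
  ## multi-start across the tested range to avoid plateau-trapped fits
  starts <- lapply(c(0, -1.5, 1.5), function(d) {
    s <- start; s[1] <- s[1] + d; s
  })
  fits <- lapply(starts, function(s)
    stats::nlminb(s, obj, control = list(iter.max = 500, eval.max = 800)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  p <- best$par
  ec50 <- 10^p[1]
  tp <- if (top_free) p[2] else top
  h <- exp(p[if (top_free) 3 else 2])
  vc <- tryCatch({
    H <- stats::optimHess(p, obj)
    dfree <- length(conc) - length(p)
    s2 <- best$objective / max(dfree, 1)
    2 * s2 * solve(H)
  }, error = function(e) NULL)
  structure(list(ec50 = ec50, top = tp, bottom = bottom, hill_slope = h,
                 sse = best$objective, vcov = vc,
                 converged = best$convergence == 0, flags = flags),
            class = "hill_fit")
}

#' Fit a competition-binding displacement curve
#'
#' Descending Hill curve on the percent-of-control-specific-binding scale,
#' `Y = bottom + (top - bottom) / (1 + ([I]/IC50)^h)`, with top/bottom fixed
#' at 100/0 unless overridden. A curve that stays flat near 100% is flagged
#' `no_displacement` and its IC50 reported as censored at the highest tested
#' concentration (a lower bound, not an estimate).
#'
#' @param conc competitor concentrations (mol/L).
#' @param percent_specific percent of control specific binding (0-100).
#' @param top,bottom fixed asymptotes (default 100 and 0).
#' @return object of class `competition_fit`: `ic50`, `hill_slope`,
#'   `ic50_censored`, `sse`, `flags`.
#' @export
fit_competition <- function(conc, percent_specific, top = 100, bottom = 0) {
  stopifnot(length(conc) == length(percent_specific), all(conc >= 0))
  pos <- conc > 0
  ## no displacement: even at the top tested concentrations binding stays
  ## near control level
  high <- conc >= stats::quantile(conc[pos], 0.75)
  if (mean(percent_specific[high]) > 0.8 * top) {
    return(structure(list(ic50 = max(conc), hill_slope = NA_real_,
                          ic50_censored = TRUE, sse = NA_real_,
                          flags = "no_displacement"),
                     class = "competition_fit"))
  }
  obj <- function(p) {
    ic50 <- 10^p[1]; h <- exp(p[2])
    mu <- bottom + (top - bottom) / (1 + (conc / ic50)^h)
    sum((mu - percent_specific)^2)
  }
  lc_mid <- log10(stats::median(conc[pos]))
  starts <- lapply(c(0, -1.5, 1.5), function(d) c(lc_mid + d, 0))
  fits <- lapply(starts, function(s)
    stats::nlminb(s, obj, control = list(iter.max = 500)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  structure(list(ic50 = 10^best$par[1], hill_slope = exp(best$par[2]),
                 ic50_censored = FALSE, sse = best$objective,
                 flags = character(0)),
            class = "competition_fit")
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + [L]/Kd)` where `[L]` is the radioligand concentration
#' and `Kd` its equilibrium dissociation constant.
#'
#' @param ic50 half-maximal inhibitory concentration (mol/L, > 0).
#' @param L radioligand concentration (mol/L, >= 0).
#' @param Kd radioligand dissociation constant (mol/L, > 0).
#' @return Ki (mol/L).
#' @export
cheng_prusoff <- function(ic50, L, Kd) {
  if (any(ic50 <= 0) || any(L < 0) || any(Kd <= 0))
    stop("cheng_prusoff: ic50 and Kd must be > 0, L >= 0")
  ic50 / (1 + L / Kd)
}
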