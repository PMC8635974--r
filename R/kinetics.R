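## Exponential-decay fitting for normalized offset traces.
##
## One-phase:  Y = (Y0 - Plateau) * exp(-K * x) + Plateau
## Two-phase:  SpanFast = (Y0 - Plateau) * %Fast * .01
##             SpanSlow = (Y0 - Plateau) * (100 - %Fast) * .01
##             Y = Plateau + SpanFast * exp(-KFast * x)
##                         + SpanSlow * exp(-KSlow * x)
## Under the constrained convention Y0 = 1 and Plateau = 0.
## Rates are kept positive by optimizing log K; %Fast by a logit.

decay_fit <- function(model, pars, sse, n, constrained, flags = character(0)) {
  structure(c(list(model = model), pars,
              list(sse = sse, n_points = n,
                   constraints_applied = if (constrained)
                     "Y0 = 1, Plateau = 0" else "none",
                   flags = flags)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s exponential decay fit (%s)\n", x$model,
              x$constraints_applied))
  if (x$model == "one_phase") {
    cat(sprintf("  K = %.6g /s (half-life %.6g s)\n", x$K, log(2) / x$K))
  } else {
    cat(sprintf("  KFast = %.6g /s, KSlow = %.6g /s, %%Fast = %.4g\n",
                x$KFast, x$KSlow, x$percent_fast))
    cat(sprintf("  SpanFast = %.6g, SpanSlow = %.6g\n",
                x$SpanFast, x$SpanSlow))
  }
  cat(sprintf("  Y0 = %.6g, Plateau = %.6g, SSE = %.6g, n = %d\n",
              x$Y0, x$Plateau, x$sse, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

## crude K estimate from a log-linear regression of (y - plateau)
init_rate <- function(t, y, plateau = 0) {
  z <- y - plateau
  keep <- z > 0
  if (sum(keep) < 2) return(0.1)
  co <- stats::lm.fit(cbind(1, t[keep]), log(z[keep]))$coefficients
  max(abs(co[2]), 1e-6)
}

#' Fit a one-phase exponential decay
#'
#' `Y = (Y0 - Plateau) * exp(-K * x) + Plateau`. With `constrain = TRUE`
#' (the convention for normalized offset traces) Y0 is fixed at 1 and the
#' plateau at 0, leaving K as the only parameter; K > 0 is enforced by
#' fitting log K. Non-decaying data is flagged `non_convergent`.
#'
#' @param t time since agonist withdrawal (s, >= 0).
#' @param y normalized trace values.
#' @param constrain fix Y0 = 1 and Plateau = 0 (default TRUE).
#' @return `decay_fit`
#' @export
fit_one_phase_decay <- function(t, y, constrain = TRUE) {
  stopifnot(length(t) == length(y), length(t) >= 4, all(t >= 0))
  flags <- character(0)
  if (constrain) {
    obj <- function(p) sum((exp(-exp(p) * t) - y)^2)
    starts <- log(c(init_rate(t, y), 0.01, 1))
    fits <- lapply(starts, function(s) stats::nlminb(s, obj))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    K <- exp(best$par)
    Y0 <- 1; Plateau <- 0; sse <- best$objective
  } else {
    obj <- function(p) {
      mu <- (p[2] - p[3]) * exp(-exp(p[1]) * t) + p[3]
      sum((mu - y)^2)
    }
    start <- c(log(init_rate(t, y, min(y))), max(y), min(y))
    best <- stats::nlminb(start, obj)
    K <- exp(best$par[1]); Y0 <- best$par[2]; Plateau <- best$par[3]
    sse <- best$objective
  }
  ## a decay slower than 1/(100 * trace length) is indistinguishable from a
  ## flat line on this window
  if (K < 1 / (100 * max(diff(range(t)), 1)))
    flags <- c(flags, "non_convergent")
  decay_fit("one_phase", list(Y0 = Y0, Plateau = Plateau, K = K),
            sse, length(t), constrain, flags)
}

#' Fit a two-phase exponential decay
#'
#' `Y = Plateau + SpanFast * exp(-KFast * x) + SpanSlow * exp(-KSlow * x)`
#' with `SpanFast = (Y0 - Plateau) * %Fast * .01` and
#' `SpanSlow = (Y0 - Plateau) * (100 - %Fast) * .01`. Under constraints
#' Y0 = 1, Plateau = 0. `KFast >= KSlow` is enforced by relabeling after the
#' fit (complementing %Fast), removing label-switching ambiguity. Fits with
#' `KFast/KSlow < 3` are flagged `practically_one_phase`; %Fast pinned at
#' 0 or 100 is flagged `degenerate`.
#'
#' @inheritParams fit_one_phase_decay
#' @return `decay_fit`
#' @export
fit_two_phase_decay <- function(t, y, constrain = TRUE) {
  stopifnot(length(t) == length(y), length(t) >= 6, all(t >= 0))
  flags <- character(0)
  n3 <- max(2L, length(t) %/% 3L)
  k_head <- init_rate(t[seq_len(n3)], y[seq_len(n3)])
  k_tail <- init_rate(utils::tail(t, n3), utils::tail(y, n3))
  model <- function(p, span) {
    kf <- exp(p[1]); ks <- exp(p[2]); pf <- stats::plogis(p[3])
    span * (pf * exp(-kf * t) + (1 - pf) * exp(-ks * t))
  }
  if (constrain) {
    obj <- function(p) sum((model(p, 1) - y)^2)
    starts <- list(c(log(max(k_head, 2 * k_tail)), log(max(k_tail, 1e-4)), 0),
                   c(log(0.5), log(0.02), 0.4),
                   c(log(10 * k_tail + 1e-3), log(k_tail + 1e-5), -0.4))
    fits <- lapply(starts, function(s)
      stats::nlminb(s, obj, control = list(iter.max = 500, eval.max = 800)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    p <- best$par
    Y0 <- 1; Plateau <- 0; sse <- best$objective
  } else {
    obj <- function(p) {
      mu <- p[5] + model(p[1:3], p[4] - p[5])
      sum((mu - y)^2)
    }
    start <- c(log(max(k_head, 2 * k_tail)), log(max(k_tail, 1e-4)), 0,
               max(y), min(y))
    best <- stats::nlminb(start, obj,
                          control = list(iter.max = 500, eval.max = 800))
    p <- best$par; Y0 <- p[4]; Plateau <- p[5]; sse <- best$objective
  }
  kf <- exp(p[1]); ks <- exp(p[2]); pf <- 100 * stats::plogis(p[3])
  if (kf < ks) {  # relabel so the fast phase is fast
    tmp <- kf; kf <- ks; ks <- tmp; pf <- 100 - pf
  }
  if (pf < 1e-6 || pf > 100 - 1e-6) flags <- c(flags, "degenerate")
  if (kf / ks < 3) flags <- c(flags, "practically_one_phase")
  span <- Y0 - Plateau
  decay_fit("two_phase",
            list(Y0 = Y0, Plateau = Plateau, KFast = kf, KSlow = ks,
                 percent_fast = pf,
                 SpanFast = span * pf * 0.01,
                 SpanSlow = span * (100 - pf) * 0.01),
            sse, length(t), constrain, flags)
}

#' Compare nested decay fits by the extra-sum-of-squares F test
#'
#' @param fit1 the simpler fit (one-phase).
#' @param fit2 the more complex fit (two-phase) on the same data.
#' @param n_points number of data points (defaults to the value recorded on
#'   the fits, which must agree).
#' @param alpha significance level for the recommendation.
#' @return list: `F`, `df1`, `df2`, `p_value`, `preferred`.
#' @export
compare_decay_models <- function(fit1, fit2, n_points = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(fit1, "decay_fit"), inherits(fit2, "decay_fit"))
  if (fit1$model != "one_phase" || fit2$model != "two_phase")
    stop("fits are not nested: expected one_phase then two_phase")
  if (is.null(n_points)) {
    if (fit1$n_points != fit2$n_points)
      stop("fits are not on identical data (different n)")
    n_points <- fit1$n_points
  }
  npar <- function(f) {
    base <- if (f$model == "one_phase") 1L else 3L
    if (f$constraints_applied == "none") base + 2L else base
  }
  p1 <- npar(fit1); p2 <- npar(fit2)
  df1 <- p2 - p1; df2 <- n_points - p2
  if (df1 <= 0 || df2 <= 0) stop("invalid degrees of freedom")
  if (fit2$sse <= 0 || fit1$sse <= fit2$sse * (1 + 1e-12)) {
    Fstat <- max(0, (fit1$sse - fit2$sse) / df1 / max(fit2$sse / df2,
                                                      .Machine$double.xmin))
    if (fit1$sse <= fit2$sse * (1 + 1e-12)) Fstat <- 0
  } else {
    Fstat <- ((fit1$sse - fit2$sse) / df1) / (fit2$sse / df2)
  }
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = df1, df2 = df2, p_value = p,
       preferred = if (p < alpha) "two_phase" else "one_phase")
}
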