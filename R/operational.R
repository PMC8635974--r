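#' Assemble an operational-model dataset for one pathway
#'
#' Bundles normalized concentration-response data with the per-agonist
#' affinities (Ki, fixed from competition binding) and the pathway's Emax
#' convention. For recruitment readouts normalized to the reference
#' agonist's maximum, Emax is 1; for readouts normalized per-well to the
#' reference maximum on a percent-like scale, Emax is the reference maximum
#' itself (supplied by the user, never hard-coded).
#'
#' @param data data.frame with columns `agonist`, `conc_M`, `response` (and
#'   optionally `replicate`).
#' @param Ki named numeric vector, mol/L, one entry per agonist.
#' @param Emax fixed system maximum response.
#' @param pathway_id label.
#' @return object of class `operational_dataset`.
#' @export
operational_dataset <- function(data, Ki, Emax = 1,
                                pathway_id = "pathway") {
  stopifnot(is.data.frame(data),
            all(c("agonist", "conc_M", "response") %in% names(data)),
            !is.null(names(Ki)), all(Ki > 0), Emax > 0)
  agonists <- unique(data$agonist)
  missing_ki <- setdiff(agonists, names(Ki))
  if (length(missing_ki))
    stop("no Ki for agonist(s): ", paste(missing_ki, collapse = ", "))
  cnt <- tapply(data$conc_M, data$agonist,
                function(x) length(unique(x)))
  if (any(cnt < 4))
    stop("every agonist needs >= 4 concentrations; offending: ",
         paste(names(cnt)[cnt < 4], collapse = ", "))
  structure(list(data = data, Ki = Ki[agonists], Emax = Emax,
                 agonists = agonists, pathway_id = pathway_id),
            class = "operational_dataset")
}

op_sse <- function(log_tau, log_n, ds, agonists) {
  n <- exp(log_n)
  sse <- 0
  for (i in seq_along(agonists)) {
    ag <- agonists[i]
    rows <- ds$data$agonist == ag
    mu <- operational_response(ds$data$conc_M[rows], exp(log_tau[i]),
                               ds$Ki[[ag]], n, ds$Emax)
    sse <- sse + sum((mu - ds$data$response[rows])^2)
  }
  sse
}

#' Global operational-model fit with shared slope and fixed affinities
#'
#' Simultaneous least-squares fit of the Black-Leff operational model over
#' all agonists of one pathway: one shared transducer slope `n`, one `tau`
#' per agonist, each agonist's `Ki` fixed from competition binding, `Emax`
#' fixed by the pathway's normalization convention. Positivity of `tau` and
#' `n` is enforced by log-parameterization. Standard errors on log10 tau and
#' n come from the curvature of the residual surface at the optimum.
#'
#' Agonists whose responses never exceed `censor_threshold * Emax` carry no
#' information about tau beyond an upper bound; they are excluded from the
#' fit (and from the shared-n estimation) and reported with `censored =
#' TRUE`, tau set to the identifiability bound implied by the threshold.
#'
#' @param ds an `operational_dataset`.
#' @param censor_threshold fraction of Emax below which an agonist counts as
#'   response-free (default 0.02).
#' @return object of class `operational_fit`: data.frame `agonists` with
#'   columns `agonist`, `tau`, `se_log10_tau`, `Ki`, `log_tau_over_ki`,
#'   `censored`; shared `n`, `se_n`, `Emax`, `sse`, `converged`.
#' @export
fit_operational_global <- function(ds, censor_threshold = 0.02) {
  stopifnot(inherits(ds, "operational_dataset"))
  peak <- vapply(ds$agonists, function(ag) {
    rows <- ds$data$agonist == ag
    max(tapply(ds$data$response[rows], ds$data$conc_M[rows], mean))
  }, numeric(1))
  censored <- peak <= censor_threshold * ds$Emax
  active <- ds$agonists[!censored]
  if (!length(active)) stop("no agonist with measurable responses")
  ## start values: tau from each agonist's apparent top,
  ## top = Emax * tau^n / (tau^n + 1) at saturating [A] (n = 1 start)
  frac <- pmin(pmax(peak[active] / ds$Emax, 1e-3), 1 - 1e-3)
  tau0 <- frac / (1 - frac)
  obj <- function(p) op_sse(p[seq_along(active)], p[length(p)], ds, active)
  start <- c(log(tau0), 0)
  fit <- stats::nlminb(start, obj,
                       control = list(iter.max = 1000, eval.max = 2000))
  ## one polish restart guards against flat-region stalls
  fit2 <- stats::nlminb(fit$par, obj,
                        control = list(iter.max = 1000, eval.max = 2000))
  if (fit2$objective < fit$objective) fit <- fit2
  p <- fit$par
  k <- length(active)
  tau <- exp(p[seq_len(k)]); n <- exp(p[k + 1])
  npoints <- sum(ds$data$agonist %in% active)
  df_residual <- max(npoints - (k + 1), 1)
  se_log <- rep(NA_real_, k + 1)
  ## standard nonlinear-regression covariance sigma^2 (J'J)^-1 with a
  ## central-difference Jacobian of the stacked residual vector
  vc <- tryCatch({
    resid_fun <- function(pp) {
      n_ <- exp(pp[k + 1])
      unlist(lapply(seq_along(active), function(i) {
        rows <- ds$data$agonist == active[i]
        operational_response(ds$data$conc_M[rows], exp(pp[i]),
                             ds$Ki[[active[i]]], n_, ds$Emax) -
          ds$data$response[rows]
      }))
    }
    h <- pmax(1e-6, 1e-6 * abs(p))
    J <- vapply(seq_along(p), function(j) {
      pu <- p; pu[j] <- pu[j] + h[j]
      pl <- p; pl[j] <- pl[j] - h[j]
      (resid_fun(pu) - resid_fun(pl)) / (2 * h[j])
    }, numeric(npoints))
    s2 <- fit$objective / df_residual
    s2 * solve(crossprod(J))
  }, error = function(e) NULL)
  if (!is.null(vc)) {
    d <- diag(vc)
    se_log[d >= 0] <- sqrt(d[d >= 0])
  }
  se_log10_tau <- se_log[seq_len(k)] / log(10)
  se_n <- se_log[k + 1] * n  # delta method from log n
  tau_all <- se_all <- stats::setNames(rep(NA_real_, length(ds$agonists)),
                                       ds$agonists)
  tau_all[active] <- tau
  se_all[active] <- se_log10_tau
  ## censored agonists: tau bounded above by the detection-limit value
  thr <- censor_threshold * ds$Emax / (ds$Emax - censor_threshold * ds$Emax)
  tau_all[censored] <- thr^(1 / n)
  agtab <- data.frame(agonist = ds$agonists,
                      tau = unname(tau_all[ds$agonists]),
                      se_log10_tau = unname(se_all[ds$agonists]),
                      Ki = unname(ds$Ki[ds$agonists]),
                      censored = unname(censored[ds$agonists]),
                      stringsAsFactors = FALSE)
  agtab$log_tau_over_ki <- log10(agtab$tau) - log10(agtab$Ki)
  structure(list(agonists = agtab, n = n, se_n = se_n, Emax = ds$Emax,
                 sse = fit$objective, df_residual = df_residual,
                 converged = fit$convergence == 0,
                 pathway_id = ds$pathway_id),
            class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("Operational-model global fit: %s\n", x$pathway_id))
  cat(sprintf("  shared n = %.4g (SE %.3g), Emax = %.4g, SSE = %.4g\n",
              x$n, x$se_n, x$Emax, x$sse))
  print(x$agonists, digits = 4)
  invisible(x)
}

#' Transduction coefficients relative to a reference agonist
#'
#' Computes `log10(tau/Ki)` per agonist and the pathway-specific bias
#' coefficient `delta log10(tau/Ki)` relative to the reference agonist. The
#' reference's delta is exactly 0. Uncertainty is the quadrature sum of the
#' two log10-tau standard errors (Ki values are fixed constants of the
#' fit). Censored agonists get an upper bound, not a point value.
#'
#' @param fit an `operational_fit`.
#' @param reference reference agonist id (default "ACh").
#' @param conf_level confidence level for the reported interval.
#' @return data.frame: `agonist`, `log_tau_over_ki`,
#'   `delta_log_tau_over_ki`, `se_delta`, `ci_lo`, `ci_hi`, `censored`,
#'   `is_reference`.
#' @export
compute_bias_factors <- function(fit, reference = "ACh",
                                 conf_level = 0.95) {
  stopifnot(inherits(fit, "operational_fit"))
  tab <- fit$agonists
  if (!reference %in% tab$agonist)
    stop("reference agonist '", reference, "' not in fit")
  ref <- tab[tab$agonist == reference, ]
  if (ref$censored) stop("reference agonist is censored; cannot scale")
  delta <- tab$log_tau_over_ki - ref$log_tau_over_ki
  se <- sqrt(tab$se_log10_tau^2 + ref$se_log10_tau^2)
  is_ref <- tab$agonist == reference
  delta[is_ref] <- 0
  se[is_ref] <- 0
  ## t-based interval on the residual degrees of freedom of the fit
  z <- if (!is.null(fit$df_residual))
    stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
  else stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(agonist = tab$agonist,
                    log_tau_over_ki = tab$log_tau_over_ki,
                    delta_log_tau_over_ki = delta,
                    se_delta = se,
                    ci_lo = delta - z * se, ci_hi = delta + z * se,
                    censored = tab$censored, is_reference = is_ref,
                    stringsAsFactors = FALSE)
  ## censored taus are upper bounds: the delta is a bound too
  out$se_delta[out$censored] <- NA_real_
  out$ci_lo[out$censored] <- -Inf
  out$ci_hi[out$censored] <- out$delta_log_tau_over_ki[out$censored]
  out
}

#' Rank agonists by efficacy with statistical tie groups
#'
#' Sorts agonists by mean efficacy (descending) and merges adjacent
#' agonists into a tie group when they are not separated by the tie rule.
#' The default rule uses Tukey-adjusted pairwise p-values on the underlying
#' per-cell values (p >= 0.05 means tied, matching the multiple-comparison
#' machinery used for the group comparisons); the fallback rule ties
#' agonists whose means differ by less than `tie_tol`.
#'
#' @param records per-cell data.frame with columns `agonist_id` and the
#'   `value` column, or an `efficacy_table` (then only the tolerance rule is
#'   available).
#' @param tie_rule "tukey" or "tolerance".
#' @param tie_tol tolerance for the fallback rule.
#' @param value value column for per-cell records.
#' @param alpha significance level of the Tukey rule.
#' @return object of class `rank_order`: data.frame (`agonist`, `mean`,
#'   `group`) sorted by mean, plus the ranking string, e.g.
#'   `"ACh > Metha ~ Fur > Are"`.
#' @export
rank_order <- function(records, tie_rule = c("tukey", "tolerance"),
                       tie_tol = 0.05, value = "normalized_amplitude",
                       alpha = 0.05) {
  tie_rule <- match.arg(tie_rule)
  if (inherits(records, "efficacy_table")) {
    means <- stats::setNames(records$mean, records$agonist)
    if (tie_rule == "tukey") {
      warning("efficacy table carries no per-cell values; ",
              "falling back to the tolerance tie rule")
      tie_rule <- "tolerance"
    }
    values <- NULL
  } else {
    stopifnot(value %in% names(records))
    values <- split(records[[value]], records$agonist_id)
    means <- vapply(values, mean, numeric(1))
  }
  ord <- order(means, decreasing = TRUE)
  ags <- names(means)[ord]
  means <- means[ord]
  tied <- function(a, b) abs(means[[a]] - means[[b]]) < tie_tol
  if (tie_rule == "tukey") {
    ## single family-wise Tukey test over all groups; adjacent pairs read
    ## off the adjusted pairwise table
    at <- tryCatch(anova_tukey(values, tukey = TRUE), error = function(e) e)
    if (inherits(at, "error")) {
      warning("Tukey tie rule unavailable (", conditionMessage(at),
              "); falling back to tolerance rule")
      tie_rule <- "tolerance"
    } else {
      pw <- at$pairwise
      tied <- function(a, b) {
        row <- (pw$group1 == a & pw$group2 == b) |
          (pw$group1 == b & pw$group2 == a)
        pw$p_adjusted[row] >= alpha
      }
    }
  }
  group <- integer(length(ags))
  g <- 1L
  group[1] <- g
  for (i in seq_along(ags)[-1]) {
    if (!tied(ags[i - 1], ags[i])) g <- g + 1L
    group[i] <- g
  }
  tab <- data.frame(agonist = ags, mean = unname(means), group = group,
                    stringsAsFactors = FALSE)
  sep <- ifelse(group[-1] == group[-length(group)], " ~ ", " > ")
  ranking <- paste0(ags[1], paste0(sep, ags[-1], collapse = ""))
  structure(list(table = tab, ranking = ranking, tie_rule = tie_rule),
            class = "rank_order")
}

#' @export
print.rank_order <- function(x, ...) {
  cat("Efficacy rank order (", x$tie_rule, " tie rule):\n  ",
      x$ranking, "\n", sep = "")
  invisible(x)
}

#' Compare efficacy rank orders between two pathways
#'
#' Identifies discordant agonist pairs: pairs whose order is reversed
#' between the two pathways with both reversals outside tie groups. Also
#' reports a rank-concordance coefficient (Kendall-type: concordant minus
#' discordant over all non-tied comparable pairs) and the 2D efficacy table
#' used for pathway-vs-pathway scatter plots.
#'
#' @param rank_a,rank_b `rank_order` objects for the two pathways.
#' @param table_a,table_b optional `efficacy_table`s (for the 2D table; mean
#'   values fall back to the rank objects).
#' @param pathway_a,pathway_b labels.
#' @return list of class `pathway_comparison`: `discordant_pairs`
#'   (data.frame), `concordance`, `n_pairs_compared`, `table_2d`.
#' @export
compare_pathways <- function(rank_a, rank_b, table_a = NULL, table_b = NULL,
                             pathway_a = "A", pathway_b = "B") {
  stopifnot(inherits(rank_a, "rank_order"), inherits(rank_b, "rank_order"))
  ta <- rank_a$table; tb <- rank_b$table
  common <- intersect(ta$agonist, tb$agonist)
  if (length(common) < 3)
    warning("fewer than 3 common agonists; concordance undefined")
  pos_a <- match(common, ta$agonist); pos_b <- match(common, tb$agonist)
  grp_a <- ta$group[pos_a]; grp_b <- tb$group[pos_b]
  pairs <- utils::combn(seq_along(common), 2)
  disc <- list(); conc_n <- 0L; comp_n <- 0L
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tied_a <- grp_a[i1] == grp_a[i2]
    tied_b <- grp_b[i1] == grp_b[i2]
    if (tied_a || tied_b) next  # tie in either pathway: not comparable
    comp_n <- comp_n + 1L
    ## positions are ranks (table sorted by mean, descending)
    dir_a <- sign(pos_a[i2] - pos_a[i1])
    dir_b <- sign(pos_b[i2] - pos_b[i1])
    if (dir_a == dir_b) {
      conc_n <- conc_n + 1L
    } else {
      disc[[length(disc) + 1L]] <- data.frame(
        agonist1 = common[i1], agonist2 = common[i2],
        order_a = ifelse(dir_a > 0, ">", "<"),
        order_b = ifelse(dir_b > 0, ">", "<"),
        stringsAsFactors = FALSE)
    }
  }
  discordant <- if (length(disc)) do.call(rbind, disc) else
    data.frame(agonist1 = character(0), agonist2 = character(0),
               order_a = character(0), order_b = character(0),
               stringsAsFactors = FALSE)
  concordance <- if (comp_n >= 1 && length(common) >= 3)
    (conc_n - nrow(discordant)) / comp_n else NA_real_
  mean_of <- function(tab, rnk) {
    if (!is.null(tab)) stats::setNames(tab$mean, tab$agonist)
    else stats::setNames(rnk$table$mean, rnk$table$agonist)
  }
  ma <- mean_of(table_a, rank_a); mb <- mean_of(table_b, rank_b)
  table_2d <- data.frame(agonist = common,
                         efficacy_a = unname(ma[common]),
                         efficacy_b = unname(mb[common]),
                         stringsAsFactors = FALSE)
  names(table_2d)[2:3] <- c(pathway_a, pathway_b)
  structure(list(pathway_a = pathway_a, pathway_b = pathway_b,
                 discordant_pairs = discordant,
                 concordance = concordance,
                 n_pairs_compared = comp_n,
                 table_2d = table_2d,
                 ranking_a = rank_a$ranking, ranking_b = rank_b$ranking),
            class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat(sprintf("Pathway comparison: %s vs %s\n", x$pathway_a, x$pathway_b))
  cat("  ", x$pathway_a, ": ", x$ranking_a, "\n", sep = "")
  cat("  ", x$pathway_b, ": ", x$ranking_b, "\n", sep = "")
  cat(sprintf("  discordant pairs: %d; concordance: %.3f\n",
              nrow(x$discordant_pairs), x$concordance))
  if (nrow(x$discordant_pairs)) print(x$discordant_pairs)
  invisible(x)
}
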