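# Assay mathematics: inhibition rate, Michaelis-Menten / Lineweaver-Burk
# fitting, inhibition-mode classification, and digestion-stability comparison.

#' ACE inhibition rate from hippuric-acid concentrations
#'
#' `100 * (HAc - HAs) / (HAc - HAH)`, where HAc, HAs and HAH are the hippuric
#' acid concentrations of the uninhibited control, the inhibited sample, and
#' the enzyme-free blank, in any one consistent unit. The rate is invariant to
#' a common rescaling of all three concentrations.
#'
#' @param ha_control Control HA concentration (no inhibitor).
#' @param ha_sample Sample HA concentration (with inhibitor).
#' @param ha_blank Blank HA concentration (no enzyme).
#' @return Inhibition rate in percent (vectorized; 0 = no inhibition,
#'   100 = full inhibition).
#' @export
#' @examples
#' inhibition_rate(10, 4, 2)   # 75
inhibition_rate <- function(ha_control, ha_sample, ha_blank) {
  vals <- cbind(ha_control, ha_sample, ha_blank)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("HA concentrations must be finite and non-negative", call. = FALSE)
  }
  denom <- ha_control - ha_blank
  if (any(denom <= 0)) {
    stop("ha_control must exceed ha_blank: the inhibition rate is undefined otherwise",
         call. = FALSE)
  }
  drop(100 * (ha_control - ha_sample) / denom)
}

#' Fit Michaelis-Menten kinetics to a substrate-velocity series
#'
#' Two routes, both exposed:
#' \describe{
#'   \item{`"lineweaver_burk"`}{ordinary least squares of 1/v on 1/S (the
#'     double-reciprocal plot); `Km = slope / intercept`,
#'     `Vmax = 1 / intercept`.}
#'   \item{`"nonlinear"`}{direct least-squares fit of
#'     `v = Vmax * S / (Km + S)` (Levenberg-Marquardt), started from the
#'     reciprocal estimates.}
#' }
#' On noiseless Michaelis-Menten data the two routes agree to numerical
#' precision; with noise the nonlinear fit weights points more evenly.
#'
#' @param substrate Substrate concentrations (>= 3 distinct positive levels;
#'   mM in the standard HHL assay).
#' @param velocity Reaction velocities (positive; HA production rate).
#' @param method `"lineweaver_burk"` (default, the classical plot) or
#'   `"nonlinear"`.
#' @param inhibitor_conc Optional inhibitor concentration label carried into
#'   the fit (any unit, used only for reporting/classification ordering).
#' @return An object of class `kinetic_fit`: `km`, `vmax`, approximate
#'   standard errors, `method`, `inhibitor_conc`.
#' @export
#' @examples
#' S <- c(0.5, 1, 2, 4, 5)
#' v <- 2 * S / (1 + S)
#' fit_mm(S, v)
fit_mm <- function(substrate, velocity,
                   method = c("lineweaver_burk", "nonlinear"),
                   inhibitor_conc = NA_real_) {
  method <- match.arg(method)
  S <- as.numeric(substrate); v <- as.numeric(velocity)
  if (length(S) != length(v)) stop("substrate and velocity lengths differ", call. = FALSE)
  if (length(unique(S)) < 3L) {
    stop("need at least 3 distinct substrate levels", call. = FALSE)
  }
  if (any(!is.finite(S)) || any(S <= 0)) stop("substrate must be positive", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) stop("velocity must be positive", call. = FALSE)

  # Reciprocal fit always computed: it is the method or the starting point.
  lb <- stats::lm(I(1 / v) ~ I(1 / S))
  a <- unname(stats::coef(lb)[1L])  # intercept = 1/Vmax
  b <- unname(stats::coef(lb)[2L])  # slope     = Km/Vmax
  if (method == "lineweaver_burk") {
    if (a <= 0) {
      stop("non-positive intercept in the double-reciprocal fit: data inconsistent with Michaelis-Menten kinetics",
           call. = FALSE)
    }
    # suppressWarnings: summary.lm warns on the (legitimate) exact-fit case
    se <- suppressWarnings(summary(lb))$coefficients[, "Std. Error"]
    vmax <- 1 / a
    km <- b / a
    # delta-method propagation, covariance between slope/intercept ignored
    vmax_se <- unname(se[1L]) / a^2
    km_se <- abs(km) * sqrt((unname(se[2L]) / b)^2 + (unname(se[1L]) / a)^2)
    fit <- list(km = km, vmax = vmax, km_se = km_se, vmax_se = vmax_se,
                method = method, inhibitor_conc = inhibitor_conc)
  } else {
    start <- if (a > 0 && b > 0) {
      list(Vmax = 1 / a, Km = b / a)
    } else {
      list(Vmax = max(v) * 1.5, Km = stats::median(S))
    }
    nl <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), start = start,
                            lower = c(Vmax = 1e-12, Km = 1e-12),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nl)
    se <- tryCatch(suppressWarnings(summary(nl))$coefficients[, "Std. Error"],
                   error = function(e) c(Vmax = NA_real_, Km = NA_real_))
    fit <- list(km = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
                km_se = unname(se["Km"]), vmax_se = unname(se["Vmax"]),
                method = method, inhibitor_conc = inhibitor_conc)
  }
  if (fit$km <= 0 || fit$vmax <= 0) {
    stop("fit produced non-positive Km or Vmax", call. = FALSE)
  }
  class(fit) <- "kinetic_fit"
  fit
}

#' @export
print.kinetic_fit <- function(x, ...) {
  lab <- if (is.na(x$inhibitor_conc)) "" else sprintf(" [I] = %g", x$inhibitor_conc)
  cat(sprintf("<kinetic_fit>%s Km = %.6g, Vmax = %.6g (%s)\n",
              lab, x$km, x$vmax, x$method))
  invisible(x)
}

#' Fit Michaelis-Menten kinetics per inhibitor concentration
#'
#' Splits a kinetic assay table by inhibitor concentration and fits each
#' series with [fit_mm()]. The zero-inhibitor series is the control.
#'
#' @param data Data frame with columns `inhibitor_conc`, `substrate_mM`,
#'   `velocity`.
#' @param method Passed to [fit_mm()].
#' @return List with `control` (a `kinetic_fit`) and `inhibited` (list of
#'   `kinetic_fit`, ascending inhibitor concentration).
#' @export
fit_inhibition_series <- function(data, method = "lineweaver_burk") {
  need <- c("inhibitor_conc", "substrate_mM", "velocity")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  concs <- sort(unique(data$inhibitor_conc))
  fits <- lapply(concs, function(ci) {
    sub <- data[data$inhibitor_conc == ci, ]
    fit_mm(sub$substrate_mM, sub$velocity, method = method, inhibitor_conc = ci)
  })
  ctrl <- which(concs == 0)
  if (length(ctrl) != 1L) {
    stop("data must contain exactly one inhibitor_conc == 0 control series",
         call. = FALSE)
  }
  list(control = fits[[ctrl]], inhibited = fits[-ctrl])
}

#' Classify the inhibition mode from apparent kinetic parameters
#'
#' Compares apparent Km and Vmax at each inhibitor concentration with the
#' uninhibited control, in the classical Lineweaver-Burk reading:
#' \itemize{
#'   \item Km up, Vmax unchanged: competitive;
#'   \item Vmax down, Km unchanged: non-competitive;
#'   \item both down with the Km/Vmax ratio preserved: uncompetitive
#'     (also called anticompetitive);
#'   \item both changed otherwise: mixed;
#'   \item neither changed at any level: none.
#' }
#' "Changed" means a relative difference beyond `tolerance` (default 20%),
#' an explicit stand-in for what is usually judged by eye on the plot. The
#' verdict is taken at the highest inhibitor concentration; if the parameter
#' changes are not monotone across concentrations a warning is raised.
#' Classification depends only on concentration ordering, so it is invariant
#' to the inhibitor unit.
#'
#' @param control `kinetic_fit` of the uninhibited series.
#' @param inhibited List of `kinetic_fit`s (or a single fit) at increasing
#'   inhibitor concentrations.
#' @param tolerance Relative-change threshold (default 0.2).
#' @return An object of class `inhibition_mode`: `mode` (one of
#'   `"competitive"`, `"non-competitive"`, `"uncompetitive"`, `"mixed"`,
#'   `"none"`) and an `evidence` data frame of per-level relative changes.
#' @export
classify_inhibition <- function(control, inhibited, tolerance = 0.2) {
  if (missing(control) || !inherits(control, "kinetic_fit")) {
    stop("a control kinetic_fit is required", call. = FALSE)
  }
  if (inherits(inhibited, "kinetic_fit")) inhibited <- list(inhibited)
  if (length(inhibited) < 1L) {
    stop("at least one inhibited kinetic_fit is required", call. = FALSE)
  }
  ord <- order(vapply(inhibited, function(f) f$inhibitor_conc, numeric(1)))
  inhibited <- inhibited[ord]
  evidence <- do.call(rbind, lapply(inhibited, function(f) {
    data.frame(inhibitor_conc = f$inhibitor_conc,
               km = f$km, vmax = f$vmax,
               km_rel_change = f$km / control$km - 1,
               vmax_rel_change = f$vmax / control$vmax - 1,
               km_vmax_ratio_rel_change =
                 (f$km / f$vmax) / (control$km / control$vmax) - 1)
  }))

  top <- evidence[nrow(evidence), ]
  km_up <- top$km_rel_change > tolerance
  km_down <- top$km_rel_change < -tolerance
  km_flat <- abs(top$km_rel_change) <= tolerance
  vmax_down <- top$vmax_rel_change < -tolerance
  vmax_flat <- abs(top$vmax_rel_change) <= tolerance
  ratio_flat <- abs(top$km_vmax_ratio_rel_change) <= tolerance

  mode <- if (km_flat && vmax_flat) {
    "none"
  } else if (km_up && vmax_flat) {
    "competitive"
  } else if (km_flat && vmax_down) {
    "non-competitive"
  } else if (km_down && vmax_down && ratio_flat) {
    "uncompetitive"
  } else {
    "mixed"
  }

  if (nrow(evidence) > 1L && mode != "none") {
    monotone <- function(x) all(diff(x) >= -1e-9) || all(diff(x) <= 1e-9)
    if (!monotone(c(0, evidence$km_rel_change)) ||
        !monotone(c(0, evidence$vmax_rel_change))) {
      warning("parameter changes are not monotone in inhibitor concentration; classification taken at the highest level",
              call. = FALSE)
    }
  }
  structure(list(mode = mode, evidence = evidence, tolerance = tolerance,
                 control = control), class = "inhibition_mode")
}

#' @export
print.inhibition_mode <- function(x, ...) {
  cat(sprintf("<inhibition_mode> %s (tolerance %g)\n", x$mode, x$tolerance))
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Lineweaver-Burk plot coordinates
#'
#' Emits the double-reciprocal data table (1/S, 1/v per inhibitor level) and
#' optionally draws the plot. Numeric results never depend on plotting.
#'
#' @param data Kinetic table as in [fit_inhibition_series()].
#' @param plot Draw a base-graphics plot (default `FALSE`).
#' @return Data frame with `inhibitor_conc`, `inv_substrate`, `inv_velocity`.
#' @export
lineweaver_burk_table <- function(data, plot = FALSE) {
  need <- c("inhibitor_conc", "substrate_mM", "velocity")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(inhibitor_conc = data$inhibitor_conc,
                    inv_substrate = 1 / data$substrate_mM,
                    inv_velocity = 1 / data$velocity)
  if (plot) {
    concs <- sort(unique(out$inhibitor_conc))
    cols <- seq_along(concs)
    graphics::plot(out$inv_substrate, out$inv_velocity,
         col = cols[match(out$inhibitor_conc, concs)], pch = 19,
         xlab = "1 / [S] (1/mM)", ylab = "1 / v",
         main = "Lineweaver-Burk plot")
    for (k in seq_along(concs)) {
      sub <- out[out$inhibitor_conc == concs[k], ]
      graphics::abline(stats::lm(inv_velocity ~ inv_substrate, data = sub),
                       col = cols[k])
    }
    graphics::legend("topleft", legend = paste("[I] =", concs),
                     col = cols, lty = 1, bty = "n")
  }
  out
}

#' Compare inhibitor potency before and after digestion
#'
#' Welch's unequal-variance two-sample comparison of replicate IC50 values
#' measured before and after simulated gastrointestinal digestion. The verdict
#' is "stable" when the difference is not significant at `alpha` \emph{and}
#' the post/pre ratio of means stays under `fold_bound`.
#'
#' @param pre_ic50,post_ic50 Replicate IC50 values (>= 3 each, same unit).
#' @param alpha Significance level (default 0.05). `alpha = 0` can never
#'   declare significance and is flagged as degenerate.
#' @param fold_bound Maximum tolerated post/pre fold change (default 2).
#' @return List with means, SDs, `p_value`, `ratio`, logical `stable`, and the
#'   settings used.
#' @export
#' @examples
#' compare_stability(c(5.1, 5.0, 4.9), c(5.2, 5.0, 5.1))$stable
compare_stability <- function(pre_ic50, post_ic50, alpha = 0.05, fold_bound = 2) {
  if (length(pre_ic50) < 3L || length(post_ic50) < 3L) {
    stop("at least 3 replicates are required in each group", call. = FALSE)
  }
  if (alpha <= 0) {
    warning("alpha <= 0 is degenerate: the test can never reject", call. = FALSE)
  }
  tt <- stats::t.test(post_ic50, pre_ic50, var.equal = FALSE)
  ratio <- mean(post_ic50) / mean(pre_ic50)
  list(mean_pre = mean(pre_ic50), sd_pre = stats::sd(pre_ic50),
       mean_post = mean(post_ic50), sd_post = stats::sd(post_ic50),
       p_value = unname(tt$p.value), ratio = ratio,
       significant = unname(tt$p.value) < alpha,
       stable = !(unname(tt$p.value) < alpha) && ratio < fold_bound,
       alpha = alpha, fold_bound = fold_bound)
}
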