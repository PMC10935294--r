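#' Fit a dose-response curve and read off the IC50
#'
#' Fits the two-parameter log-logistic model
#' `inhibition = 100 / (1 + (IC50 / c)^h)` — lower asymptote 0, upper
#' asymptote fixed at 100% — by Levenberg-Marquardt least squares. When the
#' nonlinear fit fails, the IC50 falls back to monotone log-linear
#' interpolation between the two concentrations bracketing 50%, with the
#' method recorded in the result.
#'
#' @param concentration Inhibitor concentrations (> 0, any consistent unit;
#'   at least 4 points whose inhibitions bracket the 50% level).
#' @param inhibition_pct Measured inhibition in percent (tolerated band
#'   -10..110 to admit assay noise around the asymptotes).
#' @return An object of class `dose_response`: `data`, fitted `ic50`, `hill`
#'   slope (`NA` for the interpolation fallback), `method`
#'   (`"log_logistic"` or `"interpolation"`) and residual sum of squares.
#' @export
#' @examples
#' conc <- c(0.5, 2, 5, 20, 50)
#' inh <- 100 / (1 + 5 / conc)
#' fit_dose_response(conc, inh)$ic50   # 5
fit_dose_response <- function(concentration, inhibition_pct) {
  conc <- as.numeric(concentration)
  inh <- as.numeric(inhibition_pct)
  if (length(conc) != length(inh)) {
    stop("concentration and inhibition_pct lengths differ", call. = FALSE)
  }
  if (length(conc) < 4L) stop("at least 4 dose-response points are required", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(!is.finite(inh)) || any(inh < -10) || any(inh > 110)) {
    stop("inhibition values outside the tolerated -10..110% band", call. = FALSE)
  }
  if (max(inh) < 50) {
    stop("no concentration reaches 50% inhibition: extend the upper concentration range",
         call. = FALSE)
  }
  if (min(inh) > 50) {
    stop("all concentrations exceed 50% inhibition: extend the lower concentration range",
         call. = FALSE)
  }

  interp_ic50 <- function() {
    ord <- order(conc)
    cs <- conc[ord]; is <- inh[ord]
    above <- which(is >= 50)
    lo <- max(which(is < 50)[which(is < 50) < min(above)], -Inf)
    hi <- min(above)
    if (!is.finite(lo)) lo <- hi - 1L
    if (lo < 1L) return(cs[hi])
    l1 <- log(cs[lo]); l2 <- log(cs[hi])
    exp(l1 + (50 - is[lo]) * (l2 - l1) / (is[hi] - is[lo]))
  }

  start_ic50 <- tryCatch(interp_ic50(), error = function(e) stats::median(conc))
  fit <- tryCatch({
    nl <- minpack.lm::nlsLM(inh ~ 100 / (1 + (ic50 / conc)^h),
                            start = list(ic50 = start_ic50, h = 1),
                            lower = c(ic50 = 1e-12, h = 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nl)
    list(ic50 = unname(cf["ic50"]), hill = unname(cf["h"]),
         method = "log_logistic", rss = sum(stats::resid(nl)^2))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    ic50 <- interp_ic50()
    fit <- list(ic50 = ic50, hill = NA_real_, method = "interpolation",
                rss = NA_real_)
  }
  structure(list(data = data.frame(concentration = conc, inhibition_pct = inh),
                 ic50 = fit$ic50, hill = fit$hill, method = fit$method,
                 rss = fit$rss),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> IC50 = %.6g (%s%s), %d points\n",
              x$ic50, x$method,
              if (is.na(x$hill)) "" else sprintf(", hill = %.3g", x$hill),
              nrow(x$data)))
  invisible(x)
}
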