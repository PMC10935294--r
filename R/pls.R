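# NIPALS partial least squares (PLS1) for log-IC50 QSAR.
#
# Conventions follow common chemometrics practice: X and y are autoscaled
# (mean-centred, unit variance) before component extraction; for each
# component a the X-weight is w_a = X'y / ||X'y||, the X-score t_a = X w_a,
# loadings p_a = X't_a / t_a't_a and q_a = y't_a / t_a't_a, and X and y are
# deflated by t_a p_a' and q_a t_a. The Y-side score u_a is the y-residual
# entering component a, so the inner relation u_a ~ q_a t_a has slope q_a and
# its standardized residuals are the t,u-plot outlier diagnostic.

pls_nipals <- function(X, y, n_components) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  zero_var <- which(x_scale < sqrt(.Machine$double.eps))
  x_scale[zero_var] <- 1
  y_mean <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < sqrt(.Machine$double.eps)) {
    stop("response is constant: no regression can be fitted", call. = FALSE)
  }
  Xc <- sweep(sweep(X, 2L, x_mean, "-"), 2L, x_scale, "/")
  yc <- (y - y_mean) / y_scale

  A <- n_components
  W <- P <- matrix(0, p, A)
  Tm <- U <- matrix(0, n, A)
  qv <- numeric(A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12) {
      warning(sprintf("X residual exhausted: extracted %d of %d components",
                      a - 1L, A), call. = FALSE)
      break
    }
    w <- w / wn
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; U[, a] <- yc; qv[a] <- q_a
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS component could be extracted", call. = FALSE)
  idx <- seq_len(a_done)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]; U <- U[, idx, drop = FALSE]; qv <- qv[idx]

  b_scaled <- drop(W %*% solve(crossprod(P, W), qv))
  coefficients <- b_scaled * y_scale / x_scale
  intercept <- y_mean - sum(x_mean * coefficients)
  fitted <- drop(intercept + X %*% coefficients)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - y_mean)^2)

  list(n_components = a_done, x_mean = x_mean, x_scale = x_scale,
       y_mean = y_mean, y_scale = y_scale,
       weights = W, x_loadings = P, y_loadings = qv,
       scores_t = Tm, scores_u = U,
       coefficients = coefficients, intercept = intercept,
       fitted = fitted, residuals = y - fitted,
       r2 = 1 - rss / tss, zero_variance_columns = zero_var)
}

#' Fit a PLS regression of log-IC50 on descriptors (NIPALS)
#'
#' Fits a partial least-squares regression with autoscaled X and y using the
#' NIPALS algorithm, the standard chemometrics engine for z-scale peptide QSAR.
#' Two latent components are the default. The returned coefficients and
#' intercept are on the original descriptor/response scales, so
#' `yhat = intercept + x %*% coefficients` reproduces the fitted values.
#'
#' @param X Numeric descriptor matrix (rows = training peptides).
#' @param y Numeric response (log10 IC50), `length(y) == nrow(X)`.
#' @param n_components Number of latent components (default 2).
#' @param compute_q2 Also compute leave-one-out Q2 via [loo_q2()] (default TRUE).
#' @return An object of class `pls_model`: centering/scaling constants, weights
#'   `W`, loadings `P`/`q`, scores `T`/`U`, original-scale `coefficients` and
#'   `intercept`, training `r2`, leave-one-out `q2`, indices of any
#'   zero-variance descriptor columns (flagged, kept with unit scale), and
#'   `excluded_indices` (filled by [exclude_outliers()]).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' y <- 1 + X %*% c(2, -1)
#' fit_pls(X, drop(y), n_components = 2)$r2   # noiseless: 1
fit_pls <- function(X, y, n_components = 2L, compute_q2 = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n_components <- as.integer(n_components)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (nrow(X) < n_components + 2L) {
    stop(sprintf("need at least n_components + 2 = %d training samples, got %d",
                 n_components + 2L, nrow(X)), call. = FALSE)
  }
  if (anyNA(X) || anyNA(y)) stop("X and y must be free of missing values", call. = FALSE)

  core <- pls_nipals(X, y, n_components)
  if (length(core$zero_variance_columns) > 0L) {
    message(sprintf("%d zero-variance descriptor column(s) kept with unit scale",
                    length(core$zero_variance_columns)))
  }
  model <- c(core, list(
    length_class = if (ncol(X) %% 5L == 0L) ncol(X) %/% 5L else NA_integer_,
    excluded_indices = integer(0),
    q2 = NA_real_,
    n_train = nrow(X)))
  class(model) <- "pls_model"
  if (compute_q2 && nrow(X) >= 3L) {
    model$q2 <- loo_q2(X, y, n_components = n_components)
  }
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d training samples, %d descriptors\n",
              x$n_components, x$n_train, length(x$coefficients)))
  if (!is.na(x$length_class)) {
    cat(sprintf("  peptide length class: %d\n", x$length_class))
  }
  cat(sprintf("  R2 = %.4f%s\n", x$r2,
              if (is.na(x$q2)) "" else sprintf(", Q2(LOO) = %.4f", x$q2)))
  if (length(x$excluded_indices) > 0L) {
    cat(sprintf("  excluded outliers: %s\n",
                paste(x$excluded_indices, collapse = ", ")))
  }
  invisible(x)
}

#' Leave-one-out cross-validated Q2
#'
#' Refits the PLS model n times, each time predicting the held-out sample, and
#' converts the predicted residual sum of squares to
#' `Q2 = 1 - PRESS / TSS`. Q2 near the training R2 indicates a predictive
#' model; Q2 <= 0 means no better than the mean.
#'
#' @inheritParams fit_pls
#' @return Scalar Q2.
#' @export
loo_q2 <- function(X, y, n_components = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out validation needs at least 3 samples", call. = FALSE)
  if (n - 1L < n_components + 2L) {
    stop("too few samples to refit the model with one held out", call. = FALSE)
  }
  press <- 0
  for (i in seq_len(n)) {
    core <- pls_nipals(X[-i, , drop = FALSE], y[-i], n_components)
    pred <- core$intercept + sum(X[i, ] * core$coefficients)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Standardized inner-relation residuals, one column per component:
# r_a = u_a - q_a t_a, scaled by its own SD (zero-residual components give 0).
inner_relation_residuals <- function(model) {
  R <- model$scores_u - sweep(model$scores_t, 2L, model$y_loadings, "*")
  sds <- apply(R, 2L, stats::sd)
  sds[!is.finite(sds) | sds < sqrt(.Machine$double.eps)] <- Inf
  sweep(R, 2L, sds, "/")
}

#' Exclude t,u-score outliers and refit
#'
#' Operationalizes outlier pruning on the t,u score plots: a training record is
#' flagged when its standardized inner-relation residual (per component)
#' exceeds `threshold_sd`. Flagged records are removed, the model refitted, and
#' the process repeated until no record exceeds the threshold or `max_rounds`
#' is reached. If pruning would leave fewer than `n_components + 2` samples,
#' pruning stops with a warning and the last valid model is kept.
#'
#' @param model A fitted `pls_model`.
#' @param X,y The training data the model was fitted on.
#' @param threshold_sd Flagging threshold in SD units (default 2.5;
#'   `Inf` disables pruning).
#' @param max_rounds Maximum prune-refit rounds (default 5).
#' @return List with `model` (refit, `excluded_indices` recorded against the
#'   original row order), `kept` (surviving row indices) and `excluded`.
#' @export
exclude_outliers <- function(model, X, y, threshold_sd = 2.5, max_rounds = 5L) {
  if (!inherits(model, "pls_model")) stop("model must be a pls_model", call. = FALSE)
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != model$n_train) {
    stop("X/y do not match the model's training data", call. = FALSE)
  }
  keep <- seq_len(nrow(X))
  excluded <- integer(0)
  for (round in seq_len(max_rounds)) {
    Rstd <- inner_relation_residuals(model)
    flagged <- which(apply(abs(Rstd), 1L, max) > threshold_sd)
    if (length(flagged) == 0L) break
    if (length(keep) - length(flagged) < model$n_components + 2L) {
      warning("pruning would leave too few samples; keeping last valid model",
              call. = FALSE)
      break
    }
    excluded <- c(excluded, keep[flagged])
    keep <- keep[-flagged]
    model <- fit_pls(X[keep, , drop = FALSE], y[keep],
                     n_components = model$n_components, compute_q2 = FALSE)
  }
  model$excluded_indices <- sort(excluded)
  model$q2 <- if (length(keep) >= 3L) {
    loo_q2(X[keep, , drop = FALSE], y[keep], model$n_components)
  } else {
    NA_real_
  }
  list(model = model, kept = keep, excluded = sort(excluded))
}

#' Predict IC50 for peptides from a fitted QSAR model
#'
#' For peptide input the sequence is z-scale encoded, the linear predictor
#' `intercept + x . B` gives log10 IC50, and the reported IC50 is `10^yhat`
#' (micromolar when trained on micromolar IC50). A numeric matrix `newdata`
#' returns the linear predictor directly.
#'
#' @param object A `pls_model`.
#' @param newdata Character vector of peptides (lengths must equal the model's
#'   length class) or a descriptor matrix.
#' @param ... Unused.
#' @return For peptides: data frame with `peptide`, `predicted_log10_ic50`,
#'   `predicted_ic50_uM`, `model_length_class`. For a matrix: numeric vector.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    if (is.na(object$length_class)) {
      stop("model was not trained on z-scale peptide descriptors", call. = FALSE)
    }
    lens <- nchar(newdata)
    bad <- which(lens != object$length_class)
    if (length(bad) > 0L) {
      stop(sprintf(
        "peptide '%s' has length %d; use the QSAR model for length %d peptides",
        newdata[bad[1L]], lens[bad[1L]], object$length_class), call. = FALSE)
    }
    X <- encode_peptides(newdata)
    yhat <- drop(object$intercept + X %*% object$coefficients)
    return(data.frame(peptide = newdata,
                      predicted_log10_ic50 = yhat,
                      predicted_ic50_uM = 10^yhat,
                      model_length_class = object$length_class,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata has the wrong number of descriptor columns", call. = FALSE)
  }
  drop(object$intercept + X %*% object$coefficients)
}

#' Serialize a PLS model to JSON
#'
#' Writes every field needed for bit-reproducible prediction (full-precision
#' numbers) to a documented JSON schema; [read_pls_model()] restores it.
#'
#' @param model A `pls_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  if (!inherits(model, "pls_model")) stop("model must be a pls_model", call. = FALSE)
  payload <- list(
    schema = "acescreen/pls_model/1",
    length_class = model$length_class,
    n_components = model$n_components,
    n_train = model$n_train,
    x_mean = unname(model$x_mean), x_scale = unname(model$x_scale),
    y_mean = model$y_mean, y_scale = model$y_scale,
    weights = unname(model$weights), x_loadings = unname(model$x_loadings),
    y_loadings = unname(model$y_loadings),
    scores_t = unname(model$scores_t), scores_u = unname(model$scores_u),
    coefficients = unname(model$coefficients), intercept = model$intercept,
    r2 = model$r2, q2 = model$q2,
    zero_variance_columns = model$zero_variance_columns,
    excluded_indices = model$excluded_indices)
  # 17 significant digits: lossless decimal round trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Restore a PLS model from JSON
#'
#' @param path JSON file written by [write_pls_model()].
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "acescreen/pls_model/1")) {
    stop("not an acescreen PLS model file", call. = FALSE)
  }
  model <- list(
    n_components = as.integer(p$n_components),
    x_mean = as.numeric(p$x_mean), x_scale = as.numeric(p$x_scale),
    y_mean = p$y_mean, y_scale = p$y_scale,
    weights = as.matrix(p$weights), x_loadings = as.matrix(p$x_loadings),
    y_loadings = as.numeric(p$y_loadings),
    scores_t = as.matrix(p$scores_t), scores_u = as.matrix(p$scores_u),
    coefficients = as.numeric(p$coefficients), intercept = p$intercept,
    fitted = NULL, residuals = NULL,
    r2 = p$r2, q2 = p$q2,
    zero_variance_columns = as.integer(p$zero_variance_columns),
    length_class = if (is.null(p$length_class) || is.na(p$length_class)) {
      NA_integer_
    } else {
      as.integer(p$length_class)
    },
    excluded_indices = as.integer(p$excluded_indices),
    n_train = as.integer(p$n_train))
  class(model) <- "pls_model"
  model
}
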