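#' Fit a single-response PLS (PLS1) regression
#'
#' Sequential (NIPALS-style) extraction of latent components maximising the
#' covariance between the predictors and the response. Predictors are
#' autoscaled (centred, unit variance) and the response centred before
#' extraction; coefficients are reported both on the standardised scale and
#' back-transformed to the raw predictor scale with an explicit intercept.
#' With as many components as (full-rank) predictors the fit coincides with
#' ordinary least squares.
#'
#' @param x numeric matrix or data frame of predictors (runs x variables).
#' @param y numeric response vector.
#' @param ncomp number of latent components (1 to `ncol(x)`; silently
#'   truncated at the effective rank of `x`).
#' @param scale autoscale predictors to unit variance (default `TRUE`;
#'   centring is always applied).
#' @return An object of class `pls1_fit` with elements `coefficients`
#'   (tibble: `term`, `estimate` on the raw scale, `estimate_scaled`),
#'   `intercept`, `fitted`, the calibration error `rmsec` (root mean square
#'   of the training residuals), `ncomp`, and the weight/loading matrices
#'   `W`, `P`, `q`.
#' @examples
#' d <- simulate_pls_data(seed = 1)
#' fit <- pls1_fit(d[ulva_factors()], d$y, ncomp = 4)
#' coef(fit)
#' @export
pls1_fit <- function(x, y, ncomp = NULL, scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) abort("`x` and `y` must have the same number of rows")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  p <- ncol(x)
  if (is.null(ncomp)) ncomp <- p
  if (ncomp < 1) abort("`ncomp` must be at least 1")

  mx <- colMeans(x)
  sx <- apply(x, 2, stats::sd)
  keep <- sx > 0
  if (!all(keep)) {
    warn(sprintf(
      "zero-variance predictor(s) dropped: %s",
      paste(colnames(x)[!keep], collapse = ", ")
    ))
  }
  if (!any(keep)) abort("no predictor varies")
  scl <- ifelse(keep, if (scale) sx else 1, 1)
  x0 <- sweep(sweep(x[, keep, drop = FALSE], 2, mx[keep]), 2, scl[keep], "/")
  my <- base::mean(y)
  y0 <- y - my

  pk <- ncol(x0)
  ncomp <- min(ncomp, pk, n - 1)
  W <- P <- matrix(0, pk, ncomp)
  q <- numeric(ncomp)
  Xd <- x0
  yd <- y0
  a_used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # response residual orthogonal to X: rank exhausted
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-24) break
    pvec <- drop(crossprod(Xd, tt)) / tt2
    qa <- sum(yd * tt) / tt2
    W[, a] <- w
    P[, a] <- pvec
    q[a] <- qa
    Xd <- Xd - tcrossprod(tt, pvec)
    yd <- yd - tt * qa
    a_used <- a
  }
  if (a_used == 0) abort("response has no covariance with any predictor")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]

  b_scaled_kept <- drop(W %*% solve(crossprod(P, W), q))
  b_scaled <- numeric(p)
  b_scaled[keep] <- b_scaled_kept
  b_raw <- numeric(p)
  b_raw[keep] <- b_scaled_kept / scl[keep]
  intercept <- my - sum(b_raw * mx)

  terms <- colnames(x)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  fitted <- drop(x %*% b_raw) + intercept
  structure(
    list(
      coefficients = tibble(
        term = terms,
        estimate = b_raw,
        estimate_scaled = b_scaled
      ),
      intercept = intercept,
      fitted = fitted,
      rmsec = sqrt(base::mean((fitted - y)^2)),
      ncomp = a_used,
      W = W, P = P, q = q,
      center_x = mx, scale_x = scl, center_y = my, kept = keep,
      scaled = scale
    ),
    class = "pls1_fit"
  )
}

#' @export
coef.pls1_fit <- function(object, ...) {
  setNames(
    c(object$intercept, object$coefficients$estimate),
    c("(Intercept)", object$coefficients$term)
  )
}

#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients$estimate) + object$intercept
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d component(s), %d predictor(s)\n", x$ncomp, nrow(x$coefficients)))
  print(x$coefficients)
  cat("intercept:", format(x$intercept), "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' Each sample is left out in turn, the model refit on the remainder, and the
#' left-out response predicted. Reports
#' `RMSECV = sqrt(sum((pred - meas)^2) / n_v)`, the relative error
#' `RMSE% = 100 * RMSECV / mean(y)`, the correlation between predicted and
#' measured values, and the ratio of performance to deviation
#' `RPD = sd(y) / RMSECV` (n - 1 denominator) with its interpretation band
#' ([rpd_band()]).
#'
#' @inheritParams pls1_fit
#' @return A list of class `pls1_cv`: `predictions` (tibble with `measured`,
#'   `predicted`), `rmsecv`, `rmse_pct`, `r`, `rpd`, `band`, `n`,
#'   `failed_folds`.
#' @export
loo_cv <- function(x, y, ncomp = NULL, scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) abort("leave-one-out cross-validation needs at least 3 samples")
  if (stats::sd(y) == 0) abort("degenerate response: no variance to cross-validate")
  pred <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(pls1_fit(x[-i, , drop = FALSE], y[-i], ncomp = ncomp, scale = scale)),
      error = function(e) NULL
    )
    if (is.null(fit_i)) {
      failed <- failed + 1L
      next
    }
    pred[i] <- predict(fit_i, x[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  if (!any(ok)) abort("all cross-validation folds failed")
  rmsecv <- sqrt(sum((pred[ok] - y[ok])^2) / sum(ok))
  rpd <- if (rmsecv == 0) Inf else stats::sd(y) / rmsecv
  structure(
    list(
      predictions = tibble(measured = y, predicted = pred),
      rmsecv = rmsecv,
      rmse_pct = 100 * rmsecv / base::mean(y),
      r = if (rmsecv == 0) 1 else stats::cor(pred[ok], y[ok]),
      rpd = rpd,
      band = rpd_band(rpd),
      n = n,
      failed_folds = failed
    ),
    class = "pls1_cv"
  )
}

#' @export
print.pls1_cv <- function(x, ...) {
  cat(sprintf(
    "LOO cross-validation (n = %d, %d failed fold(s))\n  RMSECV = %.4g  RMSE%% = %.3g  R = %.3f  RPD = %.3g (%s)\n",
    x$n, x$failed_folds, x$rmsecv, x$rmse_pct, x$r, x$rpd, x$band
  ))
  invisible(x)
}

#' Interpretation band of an RPD value
#'
#' Maps the ratio of performance to deviation to the conventional
#' interpretation bands: below 1.5 the model is unusable; 1.5 to 2.0 it can
#' distinguish high from low values; 2.0 to 2.5 quantitative prediction is
#' possible; above 2.5 it is excellent. Intervals are closed on the left
#' (an RPD of exactly 1.5 falls in the "distinguish" band).
#'
#' @param rpd positive RPD value (vectorised; `Inf` maps to "excellent").
#' @return Character band label.
#' @examples
#' rpd_band(2.02) # quantitative prediction possible
#' @export
rpd_band <- function(rpd) {
  if (any(rpd <= 0, na.rm = TRUE)) abort("`rpd` must be positive")
  dplyr::case_when(
    rpd < 1.5 ~ "unusable",
    rpd < 2.0 ~ "distinguish high/low",
    rpd < 2.5 ~ "quantitative prediction possible",
    TRUE ~ "excellent"
  )
}

#' Martens uncertainty test for PLS1 coefficients
#'
#' Jackknife-based significance of each predictor from the leave-one-out
#' segments: the uncertainty of a (standardised) coefficient is estimated
#' from the spread of the segment-wise coefficients around the full-model
#' coefficient, \eqn{s^2 = \frac{n-1}{n} \sum_i (b_{(-i)} - b)^2}, and a
#' predictor is flagged significant when `|b| / s` exceeds the two-sided
#' t quantile at the requested level. The procedure is deterministic for a
#' fixed dataset (segments are the ordered leave-one-out folds).
#'
#' @inheritParams pls1_fit
#' @param level confidence level for the t criterion (default 0.95).
#' @return A tibble with columns `term`, `estimate` (standardised
#'   coefficient), `jackknife_se`, `t_value`, `significant`.
#' @export
martens_uncertainty <- function(x, y, ncomp = NULL, scale = TRUE, level = 0.95) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) abort("need at least 3 samples")
  full <- suppressWarnings(pls1_fit(x, y, ncomp = ncomp, scale = scale))
  b_full <- full$coefficients$estimate_scaled
  B <- matrix(NA_real_, n, length(b_full))
  for (i in seq_len(n)) {
    fit_i <- suppressWarnings(pls1_fit(x[-i, , drop = FALSE], y[-i], ncomp = ncomp, scale = scale))
    B[i, ] <- fit_i$coefficients$estimate_scaled
  }
  s2 <- (n - 1) / n * colSums(sweep(B, 2, b_full)^2)
  se <- sqrt(s2)
  tol <- 1e-10 * max(abs(b_full), 1e-300)
  t_val <- ifelse(se > tol, abs(b_full) / se,
    ifelse(abs(b_full) > tol, Inf, 0)
  )
  tibble(
    term = full$coefficients$term,
    estimate = b_full,
    jackknife_se = se,
    t_value = t_val,
    significant = t_val > stats::qt(1 - (1 - level) / 2, df = n - 1)
  )
}

#' Log10 transform with a detection floor
#'
#' `y' = log10(max(y, floor))`, used to normalise strongly right-skewed
#' concentration distributions (which span four orders of magnitude across
#' the hydrolysis runs) before regression. The returned vector carries a
#' logical `floored` attribute recording which entries were raised to the
#' floor, so the transform is invertible except at flagged entries.
#'
#' @param y non-negative numeric vector.
#' @param floor positive floor (default 0.001, giving -3 for zeros).
#' @return Transformed vector with attribute `floored`.
#' @examples
#' log10_floor(c(100, 0)) # 2, -3
#' @export
log10_floor <- function(y, floor = 0.001) {
  if (floor <= 0) abort("`floor` must be positive")
  floored <- y < floor
  out <- log10(pmax(y, floor))
  attr(out, "floored") <- floored
  out
}

#' PLS1 analysis of one process outcome
#'
#' Regresses a process outcome on the process factors: fits the PLS1 model
#' ([pls1_fit()]), runs leave-one-out cross-validation ([loo_cv()]) and the
#' Martens uncertainty test ([martens_uncertainty()]). When `ncomp` is not
#' given it is selected by minimum RMSECV over 1 to the number of
#' predictors.
#'
#' @param data run table such as [ulva_runs()].
#' @param response outcome name; the column `response` or `<response>_mean`
#'   is used.
#' @param predictors predictor columns, default [ulva_factors()].
#' @param ncomp number of latent components, or `NULL` to select by minimum
#'   RMSECV.
#' @param transform `"none"` or `"log10"` (with `floor`) applied to the
#'   response before fitting.
#' @param floor floor for the log10 transform.
#' @return An object of class `ulva_pls` bundling `fit`, `cv`, `mut`,
#'   `ncomp` and the (possibly transformed) data. `tidy()` returns the
#'   coefficient table with significance flags, `glance()` the
#'   cross-validation statistics, `autoplot()` a predicted-vs-measured plot.
#' @examples
#' m <- pls_outcome(ulva_runs(), "yield")
#' glance(m)
#' @export
pls_outcome <- function(data, response, predictors = ulva_factors(),
                        ncomp = NULL, transform = c("none", "log10"),
                        floor = 0.001) {
  data <- as_tibble(data)
  transform <- arg_match(transform)
  ycol <- if (response %in% names(data)) response else paste0(response, "_mean")
  if (!ycol %in% names(data)) abort(sprintf("response column '%s' not found", response))
  y <- data[[ycol]]
  if (transform == "log10") y <- log10_floor(y, floor = floor)
  x <- as.matrix(data[, predictors, drop = FALSE])

  if (is.null(ncomp)) {
    cand <- seq_len(ncol(x))
    rms <- purrr::map_dbl(cand, function(a) loo_cv(x, y, ncomp = a)$rmsecv)
    ncomp <- cand[which.min(rms)]
  }
  fit <- pls1_fit(x, y, ncomp = ncomp)
  cv <- loo_cv(x, y, ncomp = ncomp)
  mut <- martens_uncertainty(x, y, ncomp = ncomp)
  structure(
    list(
      response = response, transform = transform,
      fit = fit, cv = cv, mut = mut, ncomp = ncomp,
      y = as.numeric(y), x = x
    ),
    class = "ulva_pls"
  )
}

#' @export
print.ulva_pls <- function(x, ...) {
  cat(sprintf(
    "PLS1 model of '%s' (%s response), %d component(s)\n",
    x$response, x$transform, x$ncomp
  ))
  print(x$cv)
  sig <- x$mut$term[x$mut$significant]
  cat(
    "significant predictors (Martens uncertainty):",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n"
  )
  invisible(x)
}

#' @rdname pls_outcome
#' @param x,object an `ulva_pls` object.
#' @param ... unused.
#' @method tidy ulva_pls
#' @export
tidy.ulva_pls <- function(x, ...) {
  x$fit$coefficients %>%
    left_join(
      select(x$mut, term, jackknife_se, t_value, significant),
      by = "term"
    )
}

#' @rdname pls_outcome
#' @method glance ulva_pls
#' @export
glance.ulva_pls <- function(x, ...) {
  tibble(
    response = x$response,
    transform = x$transform,
    ncomp = x$ncomp,
    rmsec = x$fit$rmsec,
    rmsecv = x$cv$rmsecv,
    rmse_pct = x$cv$rmse_pct,
    r = x$cv$r,
    rpd = x$cv$rpd,
    band = x$cv$band,
    n = x$cv$n
  )
}

#' @rdname pls_outcome
#' @method autoplot ulva_pls
#' @export
autoplot.ulva_pls <- function(object, ...) {
  ggplot2::ggplot(object$cv$predictions, ggplot2::aes(measured, predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Leave-one-out predictions: %s", object$response),
      subtitle = sprintf(
        "RMSECV = %.3g, RPD = %.2f (%s)",
        object$cv$rmsecv, object$cv$rpd, object$cv$band
      ),
      x = "measured", y = "cross-validated prediction"
    )
}
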