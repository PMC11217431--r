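
#' Natural cubic spline specification
#'
#' Describes one dimension of the cross-basis: a natural cubic spline with
#' given internal and boundary knots, optionally including an intercept
#' column. Degrees of freedom are `length(internal_knots) + 1 + intercept`.
#'
#' @param internal_knots knot positions strictly inside the boundaries.
#' @param boundary_knots length-2 numeric, the domain over which the spline
#'   is cubic; the basis is linear beyond them (natural condition).
#' @param intercept logical; include a constant column.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(internal_knots, boundary_knots, intercept = FALSE) {
  internal_knots <- sort(as.numeric(internal_knots))
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || boundary_knots[1] >= boundary_knots[2]) {
    stopf("boundary_knots must be an increasing pair")
  }
  if (length(internal_knots) &&
      (min(internal_knots) <= boundary_knots[1] ||
       max(internal_knots) >= boundary_knots[2])) {
    stopf("internal knots must lie strictly inside the boundary knots")
  }
  structure(list(internal_knots = internal_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept)),
            class = "spline_spec")
}

#' Constant (intercept-only) basis
#'
#' A single all-ones column. Used as the lag basis when the lag dimension is
#' collapsed, e.g. a single-lag window, in which case the cross-basis reduces
#' to an ordinary one-dimensional spline in exposure.
#'
#' @return An object of class `spline_spec` flagged as constant.
#' @export
constant_basis <- function() {
  structure(list(internal_knots = numeric(0), boundary_knots = c(0, 1),
                 intercept = TRUE, constant = TRUE),
            class = "spline_spec")
}

spline_df <- function(spec) {
  if (isTRUE(spec$constant)) return(1L)
  length(spec$internal_knots) + 1L + spec$intercept
}

#' Evaluate a natural cubic spline basis
#'
#' @param x numeric values at which to evaluate the basis.
#' @param spec a [spline_spec].
#' @return Matrix with `length(x)` rows and `spline_df(spec)` columns.
#'   Values outside the boundary knots are handled by linear extrapolation
#'   (the natural condition), never by error.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (isTRUE(spec$constant)) {
    m <- matrix(1, length(x), 1L)
    colnames(m) <- "b1"
    return(m)
  }
  if (length(spec$internal_knots)) {
    b <- splines::ns(x, knots = spec$internal_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  } else {
    b <- splines::ns(x, df = 1L + spec$intercept,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  }
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Internal lag knots at equally spaced log-values
#'
#' Places `nk` internal knots for the lag dimension at the exponential of
#' equally spaced points on `[log(max(l0, 1)), log(L)]`, the standard
#' construction for lag bases in distributed lag non-linear models. For the
#' default 0--2-day window with one knot this gives `sqrt(2) ~ 1.414`.
#'
#' @param lag a [lag_spec].
#' @param nk number of internal knots.
#' @return Numeric vector of lag knot positions.
#' @export
log_lag_knots <- function(lag, nk = 1L) {
  lo <- log(max(lag$l0, 1L))
  hi <- log(max(lag$L, 1L))
  if (hi <= lo) stopf("lag window too short for internal log knots")
  exp(seq(lo, hi, length.out = nk + 2L)[seq(2L, nk + 1L)])
}

#' Cross-basis specification
#'
#' Combines an exposure-dimension spline (in temperature percentiles) and a
#' lag-dimension spline into the tensor-product cross-basis of a distributed
#' lag non-linear model. The default reproduces the configuration used for
#' neonatal mortality: exposure spline with one internal knot at the 20th
#' percentile, boundary knots at 0 and 100, no intercept (2 df); lag spline
#' over lags 0--2 with one internal knot at equally spaced log-lag values
#' and an intercept (3 df); 6 coefficients in total. For very early deaths
#' an exposure knot at the 10th percentile is conventional
#' (`cross_basis_spec(var_knots = 10)`).
#'
#' @param var_knots internal knot(s) of the exposure spline (percentiles).
#' @param var_boundary exposure boundary knots (default `c(0, 100)`).
#' @param lag a [lag_spec].
#' @param lag_knots internal knot(s) of the lag spline; default
#'   [log_lag_knots].
#' @param var_spec,lag_basis_spec full [spline_spec]s overriding the
#'   shortcuts above.
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(var_knots = 20, var_boundary = c(0, 100),
                             lag = lag_spec(0L, 2L), lag_knots = NULL,
                             var_spec = NULL, lag_basis_spec = NULL) {
  stopifnot(inherits(lag, "lag_spec"))
  if (is.null(var_spec)) {
    var_spec <- spline_spec(var_knots, var_boundary, intercept = FALSE)
  }
  if (is.null(lag_basis_spec)) {
    if (lag$L == lag$l0) {
      lag_basis_spec <- constant_basis()
    } else {
      if (is.null(lag_knots)) lag_knots <- log_lag_knots(lag, 1L)
      lag_basis_spec <- spline_spec(lag_knots, c(lag$l0, lag$L), intercept = TRUE)
    }
  } else if (identical(lag_basis_spec, "constant")) {
    lag_basis_spec <- constant_basis()
  }
  df_var <- spline_df(var_spec)
  df_lag <- spline_df(lag_basis_spec)
  structure(list(var_spec = var_spec, lag_basis_spec = lag_basis_spec,
                 lag = lag, df_var = df_var, df_lag = df_lag,
                 ncoef = df_var * df_lag),
            class = "cross_basis_spec")
}

#' @export
print.cross_basis_spec <- function(x, ...) {
  cat(sprintf(
    "<cross_basis_spec> exposure df %d (knots %s), lag df %d (lags %d..%d, knots %s), %d coefficients\n",
    x$df_var, paste(signif(x$var_spec$internal_knots, 4), collapse = ","),
    x$df_lag, x$lag$l0, x$lag$L,
    paste(signif(x$lag_basis_spec$internal_knots, 4), collapse = ","),
    x$ncoef))
  invisible(x)
}

# lag basis evaluated at the integer lags of the window (rows = lags)
lag_basis_matrix <- function(spec) {
  ns_basis(seq(spec$lag$l0, spec$lag$L), spec$lag_basis_spec)
}

#' Cross-basis covariate rows for lagged exposure vectors
#'
#' For each row of lagged exposures `x = (x_{t-l0}, ..., x_{t-L})` computes
#' the tensor-product covariate vector with entries
#' `sum_l ns_var(x_{t-l})[i] * ns_lag(l)[j]`, laid out with the exposure
#' index `i` varying fastest within each lag-basis column `j`.
#'
#' @param x_lags numeric matrix (`n` cases by `L - l0 + 1` lags) or a single
#'   vector of lagged exposures.
#' @param spec a [cross_basis_spec].
#' @return Matrix `n` by `spec$ncoef`.
#' @export
cross_basis_rows <- function(x_lags, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  if (is.null(dim(x_lags))) x_lags <- matrix(x_lags, nrow = 1L)
  nl <- n_lags(spec$lag)
  if (ncol(x_lags) != nl) {
    stopf("lagged exposure vectors have %d columns; expected %d",
          ncol(x_lags), nl)
  }
  n <- nrow(x_lags)
  V <- ns_basis(as.vector(x_lags), spec$var_spec)  # (n*nl) x df_var, lag-major
  G <- lag_basis_matrix(spec)                      # nl x df_lag
  out <- matrix(0, n, spec$ncoef)
  for (k in seq_len(nl)) {
    rows <- seq.int((k - 1L) * n + 1L, k * n)
    Vk <- V[rows, , drop = FALSE]
    for (j in seq_len(spec$df_lag)) {
      cols <- (j - 1L) * spec$df_var + seq_len(spec$df_var)
      out[, cols] <- out[, cols] + Vk * G[k, j]
    }
  }
  colnames(out) <- paste0("v", rep(seq_len(spec$df_var), spec$df_lag),
                          ".l", rep(seq_len(spec$df_lag), each = spec$df_var))
  out
}

#' @rdname cross_basis_rows
#' @export
cross_basis_row <- function(x_lags, spec) {
  drop(cross_basis_rows(matrix(x_lags, nrow = 1L), spec))
}

# cross-basis rows for exposure held constant at each value of `p` across
# the whole lag window (the "overall cumulative" predictor)
cumulative_basis <- function(p, spec) {
  V <- ns_basis(p, spec$var_spec)
  g <- colSums(lag_basis_matrix(spec))
  out <- V[, rep(seq_len(spec$df_var), spec$df_lag), drop = FALSE] *
    rep(g, each = spec$df_var)[col(matrix(0, length(p), spec$ncoef))]
  colnames(out) <- paste0("v", rep(seq_len(spec$df_var), spec$df_lag),
                          ".l", rep(seq_len(spec$df_lag), each = spec$df_var))
  out
}

#' Fitted exposure-lag-response model
#'
#' Container for the cross-basis coefficients of a fitted conditional
#' logistic DLNM: coefficient vector (log odds-ratio scale), covariance
#' matrix, the minimum-mortality temperature percentile used as reference,
#' and fit statistics.
#'
#' @param spec a [cross_basis_spec].
#' @param beta coefficient vector, length `spec$ncoef`.
#' @param vcov covariance matrix of `beta`.
#' @param mmt_percentile reference percentile (minimum-mortality
#'   temperature); `NA` until [find_mmt] is run.
#' @param loglik,aic,n_sets optional fit statistics.
#' @return An object of class `exposure_response_model`.
#' @export
exposure_response_model <- function(spec, beta, vcov,
                                    mmt_percentile = NA_real_,
                                    loglik = NA_real_, aic = NA_real_,
                                    n_sets = NA_integer_) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  beta <- as.numeric(beta)
  vcov <- as.matrix(vcov)
  if (length(beta) != spec$ncoef) stopf("beta length != number of cross-basis coefficients")
  if (!all(dim(vcov) == spec$ncoef)) stopf("vcov dimensions != number of cross-basis coefficients")
  if (max(abs(vcov - t(vcov))) > 1e-8 * (1 + max(abs(vcov)))) {
    stopf("vcov is not symmetric")
  }
  structure(list(spec = spec, beta = beta, vcov = (vcov + t(vcov)) / 2,
                 mmt_percentile = mmt_percentile,
                 loglik = loglik, aic = aic, n_sets = n_sets),
            class = "exposure_response_model")
}

#' @export
print.exposure_response_model <- function(x, ...) {
  cat(sprintf("<exposure_response_model> %d coefficients, MMT percentile %s, AIC %s\n",
              x$spec$ncoef,
              ifelse(is.na(x$mmt_percentile), "unset",
                     sprintf("%.1f", x$mmt_percentile)),
              ifelse(is.na(x$aic), "NA", sprintf("%.2f", x$aic))))
  invisible(x)
}

#' Cumulative relative risk curve over the lag window
#'
#' Predicts, for each percentile on a grid, the relative risk of death for
#' exposure held at that percentile over the whole lag window, relative to
#' exposure held at the `center` percentile, with pointwise 95% confidence
#' intervals from the coefficient covariance.
#'
#' @param model an [exposure_response_model].
#' @param grid percentile grid.
#' @param center reference percentile; defaults to the model's MMT.
#' @return Data frame with columns `percentile`, `logrr`, `se`, `rr`, `lo`,
#'   `hi`; attribute `centered_at` records the reference.
#' @export
cumulative_rr <- function(model, grid = seq(1, 99, by = 0.1),
                          center = model$mmt_percentile) {
  stopifnot(inherits(model, "exposure_response_model"))
  if (is.na(center)) stopf("no center given and model MMT is unset")
  Cg <- cumulative_basis(grid, model$spec)
  Cc <- cumulative_basis(center, model$spec)
  D <- Cg - Cc[rep(1L, nrow(Cg)), , drop = FALSE]
  logrr <- drop(D %*% model$beta)
  se <- sqrt(pmax(rowSums((D %*% model$vcov) * D), 0))
  out <- data.frame(percentile = grid, logrr = logrr, se = se,
                    rr = exp(logrr),
                    lo = exp(logrr - 1.96 * se),
                    hi = exp(logrr + 1.96 * se))
  attr(out, "centered_at") <- center
  out
}

#' Locate the minimum-mortality temperature percentile
#'
#' Searches a percentile grid for the minimum of the cumulative relative
#' risk curve and records it as the model's reference (`mmt_percentile`).
#' Ties resolve to the lowest percentile. The search is invariant to the
#' centering used during fitting, since recentering shifts the whole curve
#' by a constant.
#'
#' @param model an [exposure_response_model].
#' @param step grid resolution in percentile points.
#' @param bounds search bounds; the default 1--99 avoids boundary artifacts.
#' @return The model with `mmt_percentile` set.
#' @export
find_mmt <- function(model, step = 0.1, bounds = c(1, 99)) {
  stopifnot(inherits(model, "exposure_response_model"))
  grid <- seq(bounds[1], bounds[2], by = step)
  cum <- drop(cumulative_basis(grid, model$spec) %*% model$beta)
  model$mmt_percentile <- grid[which.min(cum)]
  model
}
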