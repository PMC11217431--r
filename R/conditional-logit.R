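
#' Conditional logistic regression on matched sets
#'
#' Maximises the exact conditional likelihood for matched sets with one case
#' each: `sum_sets [eta_case - log sum_{j in set} exp(eta_j)]` with
#' `eta = X beta`, by Newton-Raphson with step-halving. The covariance is
#' the inverse observed information at the optimum.
#'
#' Uninformative sets (identical covariate rows for case and all controls)
#' contribute a constant to the likelihood and are retained so that
#' `loglik(0) = -sum_sets log(set size)` holds exactly; fitting requires at
#' least one informative set. Complete separation (a coefficient diverging
#' while the likelihood still climbs) is reported as an error rather than a
#' spurious estimate.
#'
#' @param x covariate matrix, one row per case/control day.
#' @param set integer/factor matched-set identifier per row.
#' @param case logical per row; exactly one `TRUE` per set.
#' @param init optional starting coefficients (default zero).
#' @param tol_loglik relative log-likelihood convergence tolerance.
#' @param tol_grad gradient max-norm tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `clogit_fit`: `beta`, `vcov`, `loglik`,
#'   `aic = 2k - 2 loglik`, `n_sets`, `iterations`, `grad_norm`,
#'   `converged`.
#' @export
clogit_fit <- function(x, set, case, init = NULL,
                       tol_loglik = 1e-10, tol_grad = 1e-6, max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); k <- ncol(x)
  if (length(set) != n || length(case) != n) stopf("set/case length mismatch")
  sid <- as.integer(factor(set))
  S <- max(sid)
  if (sum(case) != S || !all(tapply(case, sid, sum) == 1L)) {
    stopf("each matched set must contain exactly one case")
  }
  sizes <- tabulate(sid)
  M <- max(sizes)

  # pad sets to a rectangular S x M index matrix; slot M+... unused -> sentinel
  ord <- order(sid, !case)              # case first within each set
  pos <- sequence(sizes)                # position within set after ordering
  idx <- matrix(n + 1L, S, M)
  idx[cbind(sid[ord], pos)] <- ord
  pad <- idx > n                        # TRUE where no row

  # informative set: some row differs from the case row
  xo <- rbind(x, rep(NA_real_, k))
  informative <- rep(FALSE, S)
  for (m in seq_len(M)[-1L]) {
    d <- abs(xo[idx[, m], , drop = FALSE] - xo[idx[, 1L], , drop = FALSE])
    d[is.na(d)] <- 0
    informative <- informative | rowSums(d) > 0
  }
  if (!any(informative)) {
    stopf("all matched sets are uninformative (case and control covariates identical)")
  }

  eta_mat <- function(eta) {
    H <- matrix(c(eta, -Inf)[idx], S, M)
    H
  }
  loglik_parts <- function(beta) {
    eta <- drop(x %*% beta)
    H <- eta_mat(eta)
    mx <- do.call(pmax, as.data.frame(H))
    E <- exp(H - mx); E[pad] <- 0
    denom <- rowSums(E)
    lse <- mx + log(denom)
    ll <- sum(H[, 1L] - lse)            # column 1 holds the case
    P <- E / denom                      # within-set probabilities
    list(ll = ll, P = P)
  }
  score_info <- function(P) {
    # per-row weight p_sj scattered back to row order
    w <- numeric(n + 1L)
    w[as.vector(idx)] <- as.vector(P)
    w <- w[seq_len(n)]
    # weighted within-set mean covariates, S x k
    xbar <- matrix(0, S, k)
    for (m in seq_len(M)) {
      xm <- xo[idx[, m], , drop = FALSE]
      xm[is.na(xm)] <- 0
      xbar <- xbar + xm * P[, m]
    }
    xc <- xo[idx[, 1L], , drop = FALSE]
    grad <- colSums(xc - xbar)
    info <- crossprod(x, x * w) - crossprod(xbar)
    list(grad = grad, info = info)
  }

  beta <- if (is.null(init)) numeric(k) else as.numeric(init)
  if (length(beta) != k) stopf("init has wrong length")
  cur <- loglik_parts(beta)
  iter <- 0L; converged <- FALSE; gnorm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    si <- score_info(cur$P)
    gnorm <- max(abs(si$grad))
    step <- tryCatch(solve(si$info, si$grad),
                     error = function(e) stopf("singular information matrix"))
    halve <- 0L
    repeat {
      cand <- beta + step
      new <- loglik_parts(cand)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) stopf("step-halving failed to improve the likelihood")
    }
    improving <- new$ll > cur$ll
    rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1e-10)
    beta <- cand; cur <- new
    if (max(abs(beta)) > 50 && improving) {
      stopf("no finite MLE (separation suspected: |beta| > 50 with increasing likelihood)")
    }
    si2 <- score_info(cur$P)
    gnorm <- max(abs(si2$grad))
    if (rel < tol_loglik && gnorm < tol_grad) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  si <- score_info(cur$P)
  gnorm <- max(abs(si$grad))
  vc <- tryCatch(solve(si$info), error = function(e) stopf("singular information matrix"))
  vc <- (vc + t(vc)) / 2
  structure(list(beta = beta, vcov = vc, loglik = cur$ll,
                 aic = 2 * k - 2 * cur$ll, n_sets = S,
                 iterations = iter, grad_norm = gnorm, converged = converged),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d sets, loglik %.4f, AIC %.2f, %d iterations (grad %.2e)\n",
              x$n_sets, x$loglik, x$aic, x$iterations, x$grad_norm))
  print(x$beta)
  invisible(x)
}

#' Fit an exposure-lag-response model to matched sets
#'
#' Builds cross-basis covariates from the lagged percentile columns of
#' matched sets and fits them by conditional logistic regression. The
#' cross-basis needs no explicit centering during fitting: subtracting any
#' constant row from all covariates cancels in the conditional likelihood,
#' so the reference (MMT) can be, and is, determined afterwards with
#' [find_mmt].
#'
#' @param sets a [build_matched_sets] result.
#' @param spec a [cross_basis_spec].
#' @param locate_mmt locate the minimum-mortality percentile after fitting.
#' @param ... passed to [clogit_fit].
#' @return An [exposure_response_model].
#' @export
fit_exposure_response <- function(sets, spec = cross_basis_spec(),
                                  locate_mmt = TRUE, ...) {
  d <- matched_design(sets, spec)
  X <- cross_basis_rows(d$x_lags, spec)
  fit <- clogit_fit(X, d$set, d$case, ...)
  model <- exposure_response_model(spec, fit$beta, fit$vcov,
                                   loglik = fit$loglik, aic = fit$aic,
                                   n_sets = fit$n_sets)
  if (locate_mmt) model <- find_mmt(model)
  model
}

#' AIC selection among candidate cross-basis configurations
#'
#' Fits each candidate specification to the same matched sets and returns
#' the one with minimal AIC (ties resolve to the first candidate).
#' Candidates whose fit fails (e.g. a knot outside the span of the data
#' making the design singular) are skipped with a log message.
#'
#' @param candidates list of [cross_basis_spec]s.
#' @param sets a [build_matched_sets] result.
#' @param ... passed to [clogit_fit].
#' @return List with `best_spec`, `best_model` (MMT located), and `table`
#'   (one row per candidate: df, loglik, aic, error message if skipped).
#' @export
aic_select <- function(candidates, sets, ...) {
  if (length(candidates) < 2L) stopf("need at least two candidate specifications")
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    sp <- candidates[[i]]
    res <- tryCatch(fit_exposure_response(sets, sp, locate_mmt = FALSE, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("aic_select: candidate %d skipped (%s)", i,
                      conditionMessage(res)))
      rows[[i]] <- data.frame(candidate = i, ncoef = sp$ncoef,
                              var_knots = paste(sp$var_spec$internal_knots,
                                                collapse = ";"),
                              loglik = NA_real_, aic = NA_real_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(candidate = i, ncoef = sp$ncoef,
                              var_knots = paste(sp$var_spec$internal_knots,
                                                collapse = ";"),
                              loglik = res$loglik, aic = res$aic,
                              error = "", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$aic))) stopf("all candidate specifications failed to fit")
  best <- which.min(tab$aic)
  list(best_spec = candidates[[best]],
       best_model = find_mmt(fits[[best]]),
       table = tab)
}
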