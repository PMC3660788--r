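# Vectorised Levenberg-Marquardt engine for mono-exponential reconvolution
# fits. The amplitude enters the model linearly and is profiled out in
# closed form at each step (weighted least squares with fixed Poisson
# weights w = 1/max(counts, 1)), leaving a one-parameter LM iteration in the
# lifetime that runs simultaneously over all decays (columns of Y).
fit_tau_engine <- function(Y, cal, tau_init = NULL,
                           max_iter = 200L, rel_tol = 1e-6) {
  stopifnot(is.matrix(Y))
  n_gate <- nrow(Y); n <- ncol(Y)
  delays <- cal$gate_delays_ps
  W <- 1 / pmax(Y, 1)
  n_photons <- colSums(Y)
  active <- n_photons > 0
  tau <- if (is.null(tau_init)) tail_slope_init(Y, delays) else
    rep_len(tau_init, n)
  lo <- cal$shapes$tau_range[1] * 1.0001
  hi <- cal$shapes$tau_range[2] * 0.9999
  tau <- pmin(pmax(tau, lo), hi)
  A <- rep(NA_real_, n); ssr <- rep(Inf, n)
  converged <- rep(FALSE, n)
  lambda <- rep(1e-3, n)

  profiled <- function(tau_v, idx) {
    S <- cal$shapes$shape_fun(tau_v)
    Wi <- W[, idx, drop = FALSE]; Yi <- Y[, idx, drop = FALSE]
    A_v <- colSums(Wi * Yi * S) / pmax(colSums(Wi * S^2), 1e-300)
    R <- Yi - sweep(S, 2, A_v, "*")
    list(S = S, A = A_v, ssr = colSums(Wi * R^2), R = R)
  }

  idx <- which(active)
  if (length(idx)) {
    cur <- profiled(tau[idx], idx)
    A[idx] <- cur$A; ssr[idx] <- cur$ssr
    for (it in seq_len(max_iter)) {
      if (!length(idx)) break
      dS <- cal$shapes$dshape_fun(tau[idx])
      J <- sweep(dS, 2, A[idx], "*")
      Wi <- W[, idx, drop = FALSE]
      g <- colSums(Wi * cur$R * J)          # -1/2 d ssr / d tau
      H <- colSums(Wi * J^2)
      step <- g / (H * (1 + lambda[idx]) + 1e-300)
      tau_new <- pmin(pmax(tau[idx] + step, lo), hi)
      trial <- profiled(tau_new, idx)
      better <- trial$ssr <= cur$ssr + 1e-12
      # accept improved steps, damp the rest
      tau[idx[better]] <- tau_new[better]
      A[idx[better]] <- trial$A[better]
      ssr[idx[better]] <- trial$ssr[better]
      lambda[idx[better]] <- pmax(lambda[idx[better]] / 3, 1e-8)
      lambda[idx[!better]] <- pmin(lambda[idx[!better]] * 4, 1e8)
      done <- better & abs(step) / pmax(tau[idx], 1) < rel_tol
      converged[idx[done]] <- TRUE
      keep <- !done
      idx <- idx[keep]
      if (!length(idx)) break
      cur <- list(S = trial$S[, keep, drop = FALSE],
                  A = A[idx], ssr = ssr[idx],
                  R = Y[, idx, drop = FALSE] -
                    sweep(cal$shapes$shape_fun(tau[idx]), 2, A[idx], "*"))
    }
  }
  # standard error from the Gauss-Newton curvature at the optimum
  se <- rep(NA_real_, n)
  ok <- active & is.finite(tau)
  if (any(ok)) {
    dS <- cal$shapes$dshape_fun(tau[ok])
    J <- sweep(dS, 2, A[ok], "*")
    H <- colSums(W[, ok, drop = FALSE] * J^2)
    se[ok] <- sqrt(1 / pmax(H, 1e-300))
  }
  tau[!active] <- NA_real_
  dof <- max(n_gate - 2L, 1L)
  list(tau = tau, amplitude = A, se_tau = se,
       chi2_reduced = ssr / dof, n_photons = n_photons,
       converged = converged & active)
}

# deterministic lifetime initialisation: log-linear regression on the tail
# (last half of the gates), clamped to a sane range
tail_slope_init <- function(Y, delays) {
  n_gate <- nrow(Y)
  tail_idx <- seq(ceiling(n_gate / 2), n_gate)
  t <- delays[tail_idx]
  L <- log(pmax(Y[tail_idx, , drop = FALSE], 0.5))
  tc <- t - mean(t)
  slope <- colSums(tc * L) / sum(tc^2)
  tau <- -1 / slope
  span <- max(delays) - min(delays)
  bad <- !is.finite(tau) | tau <= 0
  tau[bad] <- span / 3
  pmin(pmax(tau, span / 50), span * 5)
}

#' Fit a single gated decay to a mono-exponential model
#'
#' Weighted Levenberg-Marquardt nonlinear least squares with reference
#' reconvolution: the model shape for a trial lifetime is built from the
#' calibrated reference (see [calibrate_reference()]) and compared to the
#' counts under Poisson weights `1/max(counts, 1)`. The amplitude is
#' profiled out analytically. At least 3 gates are required.
#'
#' @param counts Numeric vector of counts per gate.
#' @param reference A [reference_decay()] or a pre-computed
#'   [calibrate_reference()] result (pass the latter when fitting many
#'   decays against the same reference).
#' @param tau_init Optional initial lifetime (ps); default is a log-linear
#'   fit to the tail gates.
#'
#' @return An object of class `monoexp_fit`: `tau_ps`, `se_tau_ps`,
#'   `amplitude`, `chi2_reduced`, `n_photons`, `converged`, plus the data
#'   and fitted counts for inspection.
#' @export
fit_monoexp <- function(counts, reference, tau_init = NULL) {
  cal <- as_calibration(reference)
  counts <- as.numeric(counts)
  if (length(counts) < 3)
    abort("mono-exponential fitting needs at least 3 gates")
  if (length(counts) != length(cal$gate_delays_ps))
    abort("counts and reference gate schedules differ in length")
  res <- fit_tau_engine(matrix(counts, ncol = 1), cal, tau_init)
  fitted <- if (is.finite(res$tau[1]))
    res$amplitude[1] * cal$shapes$shape_fun(res$tau[1])[, 1] else
      rep(NA_real_, length(counts))
  structure(list(tau_ps = res$tau[1], se_tau_ps = res$se_tau[1],
                 amplitude = res$amplitude[1],
                 chi2_reduced = res$chi2_reduced[1],
                 n_photons = res$n_photons[1],
                 converged = res$converged[1],
                 counts = counts, fitted = fitted,
                 gate_delays_ps = cal$gate_delays_ps),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> tau = %.1f +/- %.1f ps, %g photons, chi2_red = %.3f%s\n",
    x$tau_ps, x$se_tau_ps, x$n_photons, x$chi2_reduced,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

as_calibration <- function(reference) {
  if (inherits(reference, "reference_calibration")) return(reference)
  if (inherits(reference, "reference_decay"))
    return(calibrate_reference(reference))
  abort("`reference` must be a reference_decay or reference_calibration")
}

#' Fit many gated decays at once
#'
#' Vectorised form of [fit_monoexp()]: every column of `counts` is fitted
#' independently by the same profiled Levenberg-Marquardt iteration,
#' sharing the calibrated reference. This is the engine behind
#' [fit_pixelwise()] and is convenient for simulation studies.
#'
#' @param counts Numeric matrix, one gate per row, one decay per column.
#' @param reference A [reference_decay()] or [calibrate_reference()] result.
#' @param tau_init Optional initial lifetime(s) (ps).
#' @return A tibble with one row per decay: `tau_ps`, `se_tau_ps`,
#'   `amplitude`, `n_photons`, `chi2_reduced`, `converged`.
#' @export
fit_monoexp_many <- function(counts, reference, tau_init = NULL) {
  cal <- as_calibration(reference)
  counts <- as.matrix(counts)
  if (nrow(counts) < 3)
    abort("mono-exponential fitting needs at least 3 gates")
  if (nrow(counts) != length(cal$gate_delays_ps))
    abort("counts and reference gate schedules differ in length")
  res <- fit_tau_engine(counts, cal, tau_init)
  tibble(tau_ps = res$tau, se_tau_ps = res$se_tau,
         amplitude = res$amplitude, n_photons = res$n_photons,
         chi2_reduced = res$chi2_reduced, converged = res$converged)
}

#' Pixel-wise mono-exponential lifetime image
#'
#' Fits every pixel whose total photon count reaches `threshold` to a
#' single-exponential decay (the effective "mean lifetime" per pixel);
#' pixels below threshold are left undefined. When no pixel passes the
#' threshold an empty image is returned with its `no_pixels` flag set (the
#' "no cells found" path).
#'
#' @param stack A [gated_stack()].
#' @param reference A [reference_decay()] or [calibrate_reference()] result.
#' @param threshold Minimum photons per pixel (default 200).
#'
#' @return An object of class `lifetime_image`: matrices `tau_ps`,
#'   `se_tau_ps`, `chi2_reduced` (NA where undefined), `n_photons`,
#'   `threshold`, `no_pixels`.
#' @export
fit_pixelwise <- function(stack, reference, threshold = 200) {
  stopifnot(inherits(stack, "gated_stack"), threshold >= 0)
  cal <- as_calibration(reference)
  d <- dim(stack$counts)
  if (d[1] < 3) abort("mono-exponential fitting needs at least 3 gates")
  photons <- intensity_image(stack)
  sel <- which(photons >= threshold & photons > 0)
  tau <- se <- chi2 <- matrix(NA_real_, d[2], d[3])
  if (length(sel)) {
    Y <- matrix(stack$counts, nrow = d[1])[, sel, drop = FALSE]
    res <- fit_tau_engine(Y, cal)
    keep <- res$converged
    tau[sel[keep]] <- res$tau[keep]
    se[sel[keep]] <- res$se_tau[keep]
    chi2[sel[keep]] <- res$chi2_reduced[keep]
  }
  structure(list(tau_ps = tau, se_tau_ps = se, chi2_reduced = chi2,
                 n_photons = photons, threshold = threshold,
                 no_pixels = length(sel) == 0),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  nd <- sum(is.finite(x$tau_ps))
  cat(sprintf(
    "<lifetime_image> %dx%d px, %d defined (threshold %g photons)%s\n",
    nrow(x$tau_ps), ncol(x$tau_ps), nd, x$threshold,
    if (x$no_pixels) " [no pixels above threshold]" else ""))
  invisible(x)
}

#' ROI-binned mono-exponential fit
#'
#' Sums the time-resolved counts over all pixels of a region of interest
#' (per gate) and fits the pooled decay once, as done for membrane ROIs.
#' The result is invariant to any permutation of the pixels in the ROI.
#'
#' @param stack A [gated_stack()].
#' @param reference A [reference_decay()] or [calibrate_reference()] result.
#' @param roi Logical matrix selecting the ROI pixels (non-empty).
#'
#' @return A [fit_monoexp()] result with an `n_pixels` element added.
#' @export
fit_roi_binned <- function(stack, reference, roi) {
  stopifnot(inherits(stack, "gated_stack"), is.matrix(roi))
  roi <- roi != 0
  if (!any(roi)) abort("ROI is empty")
  d <- dim(stack$counts)
  stopifnot(all(dim(roi) == d[2:3]))
  Y <- matrix(stack$counts, nrow = d[1])[, which(roi), drop = FALSE]
  pooled <- rowSums(Y)
  fit <- fit_monoexp(pooled, reference)
  fit$n_pixels <- sum(roi)
  fit
}
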