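#' Tidy a mono-exponential fit
#'
#' @param x A [fit_monoexp()] result.
#' @param ... Unused.
#' @return One-row tibble with the fitted lifetime, its standard error,
#'   amplitude, photon count, reduced chi-squared and convergence flag.
#' @export
#' @method tidy monoexp_fit
tidy.monoexp_fit <- function(x, ...) {
  tibble(tau_ps = x$tau_ps, se_tau_ps = x$se_tau_ps,
         amplitude = x$amplitude, n_photons = x$n_photons,
         chi2_reduced = x$chi2_reduced, converged = x$converged,
         n_pixels = x$n_pixels %||% NA_integer_)
}

#' @rdname tidy.monoexp_fit
#' @export
#' @method glance monoexp_fit
glance.monoexp_fit <- function(x, ...) tidy(x)

#' Tidy a pixel-wise lifetime image
#'
#' @param x A `lifetime_image`.
#' @param ... Unused.
#' @return Tibble with one row per defined pixel: `row`, `col`, `tau_ps`,
#'   `se_tau_ps`, `n_photons`, `chi2_reduced`.
#' @export
#' @method tidy lifetime_image
tidy.lifetime_image <- function(x, ...) {
  idx <- which(is.finite(x$tau_ps), arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2],
         tau_ps = x$tau_ps[idx],
         se_tau_ps = if (is.null(x$se_tau_ps)) NA_real_ else x$se_tau_ps[idx],
         n_photons = if (is.null(x$n_photons)) NA_real_ else
           x$n_photons[idx],
         chi2_reduced = if (is.null(x$chi2_reduced)) NA_real_ else
           x$chi2_reduced[idx])
}

#' Tidy / glance a global-binning fit
#'
#' `tidy()` returns the per-condition population fractions; `glance()` the
#' shared lifetimes and their flags.
#'
#' @param x A [fit_global_binned()] result.
#' @param ... Unused.
#' @export
#' @method tidy global_fit
tidy.global_fit <- function(x, ...) x$conditions

#' @rdname tidy.global_fit
#' @export
#' @method glance global_fit
glance.global_fit <- function(x, ...) {
  tibble(tau1_ps = x$tau1_ps, tau2_ps = x$tau2_ps, tau2_sd_ps = x$tau2_sd_ps,
         tau2_unidentifiable = x$tau2_unidentifiable,
         degenerate = x$degenerate)
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> tau1 = %g ps (fixed), tau2 = %.1f ps",
              x$tau1_ps, x$tau2_ps))
  if (is.finite(x$tau2_sd_ps)) cat(sprintf(" +/- %.1f ps", x$tau2_sd_ps))
  if (x$tau2_unidentifiable) cat(" [tau2 unidentifiable]")
  if (x$degenerate) cat(" [degenerate: tau2 ~ tau1]")
  cat("\n")
  print(x$conditions)
  invisible(x)
}

#' Glance at assay metrics
#'
#' @param x An [z_prime()] result.
#' @param ... Unused.
#' @export
#' @method glance assay_metrics
glance.assay_metrics <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a Hill dose-response fit
#'
#' @param x A `hill_fit` (attribute of [dose_response_table()]).
#' @param ... Unused.
#' @export
#' @method tidy hill_fit
tidy.hill_fit <- function(x, ...) {
  if (isTRUE(x$unidentifiable))
    return(tibble(ec50_uM = NA_real_, hill = NA_real_, bottom = NA_real_,
                  top = NA_real_, unidentifiable = TRUE))
  tibble(ec50_uM = x$ec50_uM, hill = x$hill, bottom = x$bottom, top = x$top,
         ec50_lo = x$ec50_ci[1], ec50_hi = x$ec50_ci[2],
         unidentifiable = FALSE)
}
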