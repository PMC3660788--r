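#' Global-binning bi-exponential analysis of a dose-response series
#'
#' Estimates the population fraction of FRETing donors underlying the
#' changes in effective mono-exponential lifetime. The decay model is
#' `I(t) = I0 [ beta1 e^(-t/tau1) + beta2 e^(-t/tau2) ]` with
#' `beta2 = 1 - beta1`, where `tau1` is the non-FRETing (long) donor
#' lifetime, fixed beforehand from a mono-exponential fit of the
#' positive-control wells. The procedure is:
#'
#' 1. pool the counts of every condition into one global decay and fit it
#'    with `tau1` fixed to obtain the shared FRET lifetime `tau2`;
#' 2. with both lifetimes fixed, fit `beta1` for each condition from that
#'    condition's pooled decay (a weighted linear problem, solved exactly).
#'
#' When a `replicate` column is present (e.g. plate rows), `tau2` is also
#' refit within each replicate and its standard deviation across replicates
#' reported. `beta1` is clamped to `[0, 1]` with a boundary flag; if the
#' fitted `tau2` approaches `tau1` within 50 ps the model is degenerate and
#' flagged, and if the short-lifetime component carries (numerically) no
#' amplitude `tau2` is flagged unidentifiable.
#'
#' @param decays A tibble with columns `condition` and `counts` (list-column
#'   of per-gate count vectors, typically pooled over the membrane ROIs of a
#'   condition's wells), optionally `replicate`.
#' @param reference A [reference_decay()] or [calibrate_reference()] result.
#' @param tau1_fixed Fixed long (non-FRETing) lifetime (ps).
#' @param tau2_range Search interval for `tau2` (ps); upper end is capped
#'   50 ps below `tau1_fixed`.
#'
#' @return An object of class `global_fit`: `tau1_ps`, `tau2_ps`,
#'   `tau2_sd_ps`, a `conditions` tibble (`condition`, `beta1`, `beta2`,
#'   `amplitude`, `chi2_reduced`, `n_photons`, `beta1_boundary`), and flags
#'   `tau2_unidentifiable`, `degenerate`.
#' @export
fit_global_binned <- function(decays, reference, tau1_fixed,
                              tau2_range = c(100, Inf)) {
  stopifnot(is.data.frame(decays),
            all(c("condition", "counts") %in% names(decays)))
  if (tau1_fixed <= 0) abort("`tau1_fixed` must be > 0")
  if (length(unique(decays$condition)) < 2)
    abort("global binning needs at least 2 conditions")
  cal <- as_calibration(reference)
  n_gate <- length(cal$gate_delays_ps)
  if (n_gate < 5)
    abort("bi-exponential fitting with fixed tau1 needs at least 5 gates")
  bad_len <- vapply(decays$counts, length, integer(1)) != n_gate
  if (any(bad_len)) abort("every decay must have one count per gate")

  pool <- function(rows) Reduce(`+`, decays$counts[rows])
  global <- pool(seq_len(nrow(decays)))

  hi <- min(tau2_range[2], tau1_fixed - 50)
  lo <- max(tau2_range[1], cal$shapes$tau_range[1] * 1.001)
  if (hi <= lo) abort("empty tau2 search interval")

  s1 <- cal$shapes$shape_fun(tau1_fixed)[, 1]
  fit_tau2 <- function(y) {
    obj <- function(tau2) biexp_linear(y, s1, cal$shapes$shape_fun(tau2)[, 1],
                                       tau1_fixed, tau2)$ssr
    opt <- optimize(obj, c(lo, hi), tol = 1e-2)
    opt$minimum
  }
  tau2 <- fit_tau2(global)
  s2 <- cal$shapes$shape_fun(tau2)[, 1]
  gfit <- biexp_linear(global, s1, s2, tau1_fixed, tau2)

  # amplitude fraction of the tau2 component in the pooled decay; if it is
  # numerically zero the data contain no short component and tau2 means
  # nothing
  tau2_unidentifiable <- gfit$beta1 > 1 - 1e-3
  degenerate <- (tau1_fixed - tau2) < 50 + 1e-9

  conditions <- unique(decays$condition)
  cond_rows <- lapply(conditions, function(cn) {
    y <- pool(which(decays$condition == cn))
    bf <- biexp_linear(y, s1, s2, tau1_fixed, tau2)
    tibble(condition = cn, beta1 = bf$beta1, beta2 = 1 - bf$beta1,
           amplitude = bf$amplitude,
           chi2_reduced = bf$ssr / max(n_gate - 2L, 1L),
           n_photons = sum(y), beta1_boundary = bf$boundary)
  })

  tau2_sd <- NA_real_
  if ("replicate" %in% names(decays) &&
      length(unique(decays$replicate)) > 1) {
    reps <- unique(decays$replicate)
    t2r <- vapply(reps, function(r) {
      fit_tau2(pool(which(decays$replicate == r)))
    }, numeric(1))
    tau2_sd <- sd(t2r)
  }

  structure(list(tau1_ps = tau1_fixed, tau2_ps = tau2, tau2_sd_ps = tau2_sd,
                 conditions = dplyr::bind_rows(cond_rows),
                 tau2_unidentifiable = tau2_unidentifiable,
                 degenerate = degenerate),
            class = "global_fit")
}

# Exact weighted least squares for y ~ a1 s1 + a2 s2 (Poisson weights),
# with non-negative amplitudes enforced by refitting on the boundary.
# The unit-sum shapes make a1, a2 photon totals of each component; the
# reported beta1 is the amplitude fraction (a component's photon yield is
# proportional to beta_i tau_i, so amplitudes are recovered as a_i / tau_i).
biexp_linear <- function(y, s1, s2, tau1, tau2) {
  w <- 1 / pmax(y, 1)
  m11 <- sum(w * s1 * s1); m12 <- sum(w * s1 * s2); m22 <- sum(w * s2 * s2)
  b1 <- sum(w * s1 * y); b2 <- sum(w * s2 * y)
  det <- m11 * m22 - m12^2
  boundary <- FALSE
  if (abs(det) < 1e-300) {
    a <- c(b1 / m11, 0); boundary <- TRUE
  } else {
    a <- c((m22 * b1 - m12 * b2) / det, (m11 * b2 - m12 * b1) / det)
  }
  if (any(a < 0)) {
    boundary <- TRUE
    ssr1 <- sum(w * (y - (b1 / m11) * s1)^2)
    ssr2 <- sum(w * (y - (b2 / m22) * s2)^2)
    a <- if (ssr1 <= ssr2) c(b1 / m11, 0) else c(0, b2 / m22)
    a <- pmax(a, 0)
  }
  resid <- y - a[1] * s1 - a[2] * s2
  beta1 <- if (sum(a) > 0) {
    b <- photon_to_amplitude_fractions(a / sum(a), c(tau1, tau2))[1]
    bc <- min(max(b, 0), 1)
    if (bc != b) boundary <- TRUE
    bc
  } else NA_real_
  list(a = a, amplitude = sum(a), ssr = sum(w * resid^2),
       beta1 = beta1, boundary = boundary)
}
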