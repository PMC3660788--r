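#' Hill dose-response model for the FRETing donor fraction
#'
#' Links an inhibitor concentration to the ground-truth fraction of FRETing
#' donors. Inhibition of myristoylation suppresses membrane binding and hence
#' aggregation, so the FRETing fraction falls from `f_max` (no inhibitor,
#' vehicle only) towards `f_min` (full inhibition, the level of residual
#' cytoplasmic dimerisation) as dose increases.
#'
#' @param ec50 Half-maximal inhibitor concentration (uM), > 0.
#' @param hill Hill slope (unitless), > 0.
#' @param f_max Maximal FRETing donor fraction, in `[0, 1]`.
#' @param f_min Residual FRETing fraction at saturating dose, `0 <= f_min <= f_max`.
#'
#' @return An object of class `dose_response_model`.
#' @export
#' @examples
#' m <- dose_response_model(ec50 = 0.1, hill = 1, f_max = 0.8, f_min = 0)
#' fret_fraction_at_dose(c(0, 0.1, 1), m)
dose_response_model <- function(ec50 = 0.1, hill = 1, f_max = 0.8, f_min = 0.05) {
  stopifnot(is.numeric(ec50), length(ec50) == 1, is.finite(ec50),
            is.numeric(hill), length(hill) == 1, is.finite(hill),
            is.numeric(f_max), length(f_max) == 1,
            is.numeric(f_min), length(f_min) == 1)
  if (ec50 <= 0) abort("`ec50` must be > 0")
  if (hill <= 0) abort("`hill` must be > 0")
  if (f_min < 0 || f_max > 1 || f_min > f_max)
    abort("need 0 <= f_min <= f_max <= 1")
  structure(list(ec50 = ec50, hill = hill, f_max = f_max, f_min = f_min),
            class = "dose_response_model")
}

#' @export
print.dose_response_model <- function(x, ...) {
  cat(sprintf(
    "<dose_response_model> EC50 = %g uM, hill = %g, f in [%g, %g]\n",
    x$ec50, x$hill, x$f_min, x$f_max))
  invisible(x)
}

#' Ground-truth FRETing donor fraction at a dose
#'
#' Evaluates the Hill curve
#' `f(d) = f_min + (f_max - f_min) / (1 + (d / ec50)^hill)`,
#' which equals `f_max` at zero dose and decreases monotonically towards
#' `f_min` with increasing dose.
#'
#' @param dose Inhibitor concentration(s), uM, non-negative.
#' @param model A [dose_response_model()].
#'
#' @return Numeric vector of fractions in `[0, 1]`, same length as `dose`.
#' @export
fret_fraction_at_dose <- function(dose, model) {
  stopifnot(inherits(model, "dose_response_model"), is.numeric(dose))
  if (any(!is.finite(dose)) || any(dose < 0))
    abort("`dose` must be finite and >= 0")
  model$f_min + (model$f_max - model$f_min) /
    (1 + (dose / model$ec50)^model$hill)
}

#' Dose at which the inhibition effect reaches a given level
#'
#' Inverse of the Hill curve in effect space: `effect = 0` corresponds to the
#' uninhibited fraction `f_max`, `effect = 1` to the fully inhibited `f_min`.
#' `dose_at_effect(0.5, m)` returns the EC50; `dose_at_effect(0.2, m)` the
#' EC20, and so on.
#'
#' @param effect Fractional effect level(s) strictly inside `(0, 1)`.
#' @inheritParams fret_fraction_at_dose
#' @return Dose(s) in uM.
#' @export
dose_at_effect <- function(effect, model) {
  stopifnot(inherits(model, "dose_response_model"), is.numeric(effect))
  if (any(effect <= 0) || any(effect >= 1))
    abort("`effect` must lie strictly between 0 and 1")
  model$ec50 * (effect / (1 - effect))^(1 / model$hill)
}
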