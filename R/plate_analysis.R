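#' Aggregate per-FOV lifetime values to a well result
#'
#' @param values A tibble with columns `well`, `fov` and `value` (per-pixel
#'   or per-ROI lifetimes, ps). Wells with no rows are absent; wells whose
#'   rows are all `NA` are flagged `no_cells`.
#' @param method `"pixel_pooled"` averages all defined values across FOVs;
#'   `"fov_mean"` averages the per-FOV means. The pooled mean equals the
#'   count-weighted mean of the per-FOV means.
#'
#' @return A tibble with one row per well: `well`, `mean_tau`, `sd_tau`,
#'   `n`, `n_fovs`, `no_cells`.
#' @export
well_aggregate <- function(values, method = c("pixel_pooled", "fov_mean")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(values),
            all(c("well", "fov", "value") %in% names(values)))
  per_fov <- values |>
    dplyr::group_by(.data$well, .data$fov) |>
    dplyr::summarise(fov_mean = mean(.data$value, na.rm = TRUE),
                     fov_n = sum(is.finite(.data$value)), .groups = "drop")
  if (method == "pixel_pooled") {
    out <- values |>
      dplyr::group_by(.data$well) |>
      dplyr::summarise(
        mean_tau = mean(.data$value, na.rm = TRUE),
        sd_tau = sd(.data$value, na.rm = TRUE),
        n = sum(is.finite(.data$value)), .groups = "drop")
  } else {
    out <- per_fov |>
      dplyr::filter(.data$fov_n > 0) |>
      dplyr::group_by(.data$well) |>
      dplyr::summarise(mean_tau = mean(.data$fov_mean),
                       sd_tau = sd(.data$fov_mean),
                       n = sum(.data$fov_n), .groups = "drop")
  }
  fov_counts <- per_fov |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(n_fovs = dplyr::n(), .groups = "drop")
  all_wells <- dplyr::distinct(values, .data$well)
  all_wells |>
    dplyr::left_join(out, by = "well") |>
    dplyr::left_join(fov_counts, by = "well") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      sd_tau = ifelse(.data$n == 1, 0, .data$sd_tau),
      no_cells = .data$n == 0,
      mean_tau = ifelse(.data$no_cells, NA_real_, .data$mean_tau))
}

#' Plate map of per-well values
#'
#' Expands well results onto the full plate grid. Wells without data are
#' flagged missing ("no cells found"); excluded wells (e.g. background/IRF
#' service wells) are carried with their role.
#'
#' @param well_results Output of [well_aggregate()] (or any tibble with
#'   `well` and a value column).
#' @param layout A [plate_layout()].
#' @param value Name of the value column (default `"mean_tau"`).
#' @return A tibble of class `plate_map` with one row per well of the plate.
#' @export
plate_map <- function(well_results, layout, value = "mean_tau") {
  stopifnot(inherits(layout, "plate_layout"))
  grid <- as_tibble(layout)
  out <- grid |>
    dplyr::left_join(
      dplyr::select(well_results, "well",
                    value = dplyr::all_of(value),
                    dplyr::any_of("no_cells")),
      by = "well") |>
    dplyr::mutate(
      excluded = .data$role == "excluded",
      missing = !.data$excluded & (is.na(.data$value)),
      value = ifelse(.data$excluded, NA_real_, .data$value))
  structure(out, class = c("plate_map", class(out)),
            rows = attr(layout, "rows"), cols = attr(layout, "cols"))
}

#' Column- and row-order drift check
#'
#' Orders the wells of one condition column-wise (left to right) and
#' row-wise (top to bottom) and fits an ordinary least-squares line to each
#' ordered series of well means, to reveal systematic spatial drift or edge
#' effects. When `assay_window` is supplied, a series is flagged when the
#' fitted drift across its span exceeds `flag_fraction` of the window.
#'
#' @param well_results Output of [well_aggregate()].
#' @param layout A [plate_layout()].
#' @param condition Condition label to inspect.
#' @param assay_window Optional assay window (ps) for flagging.
#' @param flag_fraction Fraction of the window tolerated (default 0.25).
#'
#' @return A list with `series` (tibble: direction, position, well,
#'   mean_tau) and `slopes` (tibble: direction, slope, se, n, flagged).
#' @export
drift_check <- function(well_results, layout, condition,
                        assay_window = NULL, flag_fraction = 0.25) {
  stopifnot(inherits(layout, "plate_layout"))
  sel <- as_tibble(layout) |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::inner_join(well_results, by = "well") |>
    dplyr::filter(is.finite(.data$mean_tau))
  series <- dplyr::bind_rows(
    sel |> dplyr::arrange(.data$col, .data$row) |>
      dplyr::mutate(direction = "column_wise", position = dplyr::row_number()),
    sel |> dplyr::arrange(.data$row, .data$col) |>
      dplyr::mutate(direction = "row_wise", position = dplyr::row_number())) |>
    dplyr::select("direction", "position", "well", "mean_tau")
  slopes <- series |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3)
        return(tibble(slope = NA_real_, se = NA_real_, n = nrow(d)))
      fit <- lm(mean_tau ~ position, data = d)
      sxx <- sum((d$position - mean(d$position))^2)
      se <- sqrt(sum(stats::residuals(fit)^2) / (nrow(d) - 2) / sxx)
      tibble(slope = unname(coef(fit)[2]), se = se, n = nrow(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      span_drift = .data$slope * (.data$n - 1),
      flagged = if (is.null(assay_window)) NA else
        abs(.data$span_drift) > flag_fraction * abs(assay_window))
  list(series = series, slopes = slopes)
}

#' Percent inhibition of the medium dose
#'
#' `100 * (tau_med - tau_low) / (tau_high - tau_low)`: the low dose anchors
#' 0 % and the high dose 100 % (lifetime rises as inhibition suppresses
#' FRET). Values outside `[0, 100]` are reported unclamped, with the
#' `out_of_range` attribute set.
#'
#' @param tau_med,tau_low,tau_high Lifetimes (ps) of the medium, low and
#'   high doses; `tau_high` must differ from `tau_low`.
#' @return Numeric percent inhibition with attribute `out_of_range`.
#' @export
percent_inhibition <- function(tau_med, tau_low, tau_high) {
  if (any(tau_high == tau_low))
    abort("undefined: tau_high equals tau_low")
  p <- 100 * (tau_med - tau_low) / (tau_high - tau_low)
  structure(p, out_of_range = p < 0 | p > 100)
}

#' Z-prime assay quality factor
#'
#' `Z' = 1 - 3 (sigma_pos + sigma_neg) / |mu_pos - mu_neg|` with sample
#' standard deviations; values above 0.4 are conventionally considered
#' desirable for a screening assay. Arms are typically per-well mean
#' lifetimes of the control columns; any other arm (e.g. a dose column
#' substituted for a failed control) can be passed instead.
#'
#' @param pos,neg Numeric vectors (>= 2 values each) for the positive and
#'   negative control arms.
#' @return An object of class `assay_metrics`: `mu_pos`, `sigma_pos`,
#'   `mu_neg`, `sigma_neg`, `z_prime`, `n_pos`, `n_neg`.
#' @export
z_prime <- function(pos, neg) {
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 2 || length(neg) < 2)
    abort("each arm needs at least 2 finite values")
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n)
    abort("undefined: positive and negative means are equal")
  zp <- 1 - 3 * (sd(pos) + sd(neg)) / abs(mu_p - mu_n)
  structure(list(mu_pos = mu_p, sigma_pos = sd(pos),
                 mu_neg = mu_n, sigma_neg = sd(neg),
                 z_prime = zp, n_pos = length(pos), n_neg = length(neg)),
            class = "assay_metrics")
}

#' @export
print.assay_metrics <- function(x, ...) {
  cat(sprintf(
    "<assay_metrics> Z' = %.3f  (pos %.1f +/- %.1f, neg %.1f +/- %.1f)\n",
    x$z_prime, x$mu_pos, x$sigma_pos, x$mu_neg, x$sigma_neg))
  invisible(x)
}

#' Dose-response table with optional Hill fit
#'
#' Pools all repeat wells of each dose into one row (mean +/- SD of the
#' per-well values) and optionally fits a 4-parameter Hill curve of
#' response versus log dose by nonlinear least squares, reporting the EC50
#' with a residual-bootstrap confidence interval. A flat response (fitted
#' span indistinguishable from the residual noise) is flagged
#' unidentifiable.
#'
#' @param well_results Output of [well_aggregate()] (or a tibble with
#'   `well` and the value column).
#' @param layout A [plate_layout()]; rows with role `"dose"` enter the
#'   table.
#' @param value Value column name (default `"mean_tau"`).
#' @param fit Fit the Hill curve? (default `TRUE`; needs >= 4 dose levels).
#' @param n_boot Residual bootstrap replicates for the EC50 CI.
#' @param seed RNG seed for the bootstrap.
#'
#' @return A tibble of class `dose_response` (`dose_uM`, `mean`, `sd`,
#'   `n_wells`), with the Hill fit (class `hill_fit`) in attribute
#'   `hill_fit` when fitted.
#' @export
dose_response_table <- function(well_results, layout, value = "mean_tau",
                                fit = TRUE, n_boot = 199, seed = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  d <- as_tibble(layout) |>
    dplyr::filter(.data$role == "dose") |>
    dplyr::inner_join(well_results, by = "well") |>
    dplyr::rename(value = dplyr::all_of(value)) |>
    dplyr::filter(is.finite(.data$value))
  if (length(unique(d$dose_uM)) < 2)
    abort("dose-response needs at least 2 dose levels")
  tab <- d |>
    dplyr::group_by(dose_uM = .data$dose_uM) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n_wells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$dose_uM)
  hf <- NULL
  if (fit && nrow(tab) >= 4)
    hf <- fit_hill(d$dose_uM, d$value, n_boot = n_boot, seed = seed)
  structure(tab, class = c("dose_response", class(tab)), hill_fit = hf)
}

# 4-parameter Hill fit of response vs dose (response rising with dose):
# y = bottom + (top - bottom) / (1 + (ec50/d)^hill), log-EC50 parameterised
fit_hill <- function(dose, y, n_boot = 199, seed = NULL) {
  ok <- is.finite(dose) & is.finite(y) & dose > 0
  dose <- dose[ok]; y <- y[ok]
  df <- data.frame(dose = dose, y = y)
  start <- list(bottom = min(y), top = max(y),
                lec50 = mean(log(range(dose))), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (exp(lec50) / dose)^hill),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(unidentifiable = TRUE, ec50_uM = NA_real_),
                     class = "hill_fit"))
  p <- coef(fit)
  resid_sd <- sd(stats::residuals(fit))
  unident <- abs(p["top"] - p["bottom"]) < 2 * resid_sd
  ec50_boot <- rep(NA_real_, 0)
  if (!unident && n_boot > 0) {
    fitted_v <- stats::fitted(fit)
    res <- stats::residuals(fit)
    ec50_boot <- with_seed_maybe(seed, vapply(seq_len(n_boot), function(b) {
      yb <- fitted_v + sample(res, replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nlsLM(
          yb ~ bottom + (top - bottom) / (1 + (exp(lec50) / dose)^hill),
          data = data.frame(dose = dose, yb = yb), start = as.list(p),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else exp(coef(fb)["lec50"])
    }, numeric(1)))
  }
  structure(list(
    bottom = unname(p["bottom"]), top = unname(p["top"]),
    ec50_uM = unname(exp(p["lec50"])), hill = unname(p["hill"]),
    ec50_ci = if (length(ec50_boot))
      unname(quantile(ec50_boot, c(0.025, 0.975), na.rm = TRUE)) else
        c(NA_real_, NA_real_),
    resid_sd = resid_sd, unidentifiable = unident,
    fit = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat("<hill_fit> unidentifiable (flat response)\n")
  } else {
    cat(sprintf(
      "<hill_fit> EC50 = %.4g uM [%.4g, %.4g], hill = %.2f, span %.1f-%.1f\n",
      x$ec50_uM, x$ec50_ci[1], x$ec50_ci[2], x$hill, x$bottom, x$top))
  }
  invisible(x)
}
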