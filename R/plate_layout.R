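#' Plate layout
#'
#' A tibble describing every well of a multiwell plate: its identifier
#' (letter row + number column, "A1" ... "H12"), grid position, biological
#' condition, inhibitor dose and role. Roles are `positive_control` (no-FRET
#' control, e.g. a myristoylation-deficient mutant that cannot reach the
#' membrane), `negative_control` (vehicle only, maximal FRET), `dose`
#' (inhibitor dilution series) and `excluded` (empty or service wells).
#'
#' @param wells A data frame with columns `well`, `row`, `col`, `condition`,
#'   `dose_uM`, `role`.
#' @param rows,cols Plate geometry the layout must cover.
#'
#' @return A tibble of class `plate_layout`.
#' @export
plate_layout <- function(wells, rows = 8L, cols = 12L) {
  wells <- as_tibble(wells)
  need <- c("well", "row", "col", "condition", "dose_uM", "role")
  if (!all(need %in% names(wells)))
    abort(paste("layout needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(wells$well)) abort("well ids must be unique")
  bad <- setdiff(unique(wells$role),
                 c("positive_control", "negative_control", "dose", "excluded"))
  if (length(bad))
    abort(paste("unknown well role(s):", paste(bad, collapse = ", ")))
  if (any(wells$row < 1 | wells$row > rows | wells$col < 1 | wells$col > cols))
    abort("well positions outside the plate geometry")
  structure(wells, class = c("plate_layout", class(wells)),
            rows = as.integer(rows), cols = as.integer(cols))
}

well_name <- function(row, col) paste0(LETTERS[row], col)

#' Dose-response plate layout
#'
#' The standard dose-response plating scheme: positive controls in column 1,
#' a nine-point inhibitor dilution series across columns 2-10 (default 10 uM
#' down to 0.001 uM in equal log steps, consecutive ratio 10^(4/8)), vehicle
#' (negative control, dose 0) in column 11 and column 12 excluded.
#'
#' @param rows,cols Plate geometry.
#' @param doses Dose series for columns 2-10 (uM), high to low.
#' @param condition Condition label for the dosed wells.
#' @return A [plate_layout()].
#' @export
plate_layout_dose_response <- function(rows = 8L, cols = 12L,
                                       doses = 10^seq(1, -3, length.out = 9),
                                       condition = "gag") {
  stopifnot(length(doses) == 9, cols >= 11)
  grid <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  wells <- dplyr::mutate(
    grid,
    well = well_name(.data$row, .data$col),
    role = dplyr::case_when(
      .data$col == 1 ~ "positive_control",
      .data$col >= 2 & .data$col <= 10 ~ "dose",
      .data$col == 11 ~ "negative_control",
      TRUE ~ "excluded"),
    dose_uM = dplyr::case_when(
      .data$role == "dose" ~ doses[pmax(.data$col - 1, 1)],
      .data$role == "negative_control" ~ 0,
      TRUE ~ NA_real_),
    condition = dplyr::case_when(
      .data$role == "positive_control" ~ "myr_minus",
      .data$role == "excluded" ~ NA_character_,
      TRUE ~ condition))
  plate_layout(wells[, c("well", "row", "col", "condition", "dose_uM", "role")],
               rows, cols)
}

#' Assay-characterisation plate layout (three repeated doses)
#'
#' Columns 2-10 cycle through three fixed doses (low ~EC20, medium
#' ~EC25-EC75, high ~EC80) in a configurable order, as used to check for
#' plate drift and edge effects and to compute percent inhibition of the
#' medium dose relative to the high and low doses. Column 1 holds positive
#' controls, column 11 vehicle, column 12 is excluded.
#'
#' @param doses Named numeric vector `c(low = , medium = , high = )` in uM.
#' @param pattern Order in which the three doses repeat across columns 2-10.
#' @param rows,cols Plate geometry.
#' @return A [plate_layout()].
#' @export
plate_layout_characterisation <- function(doses,
                                          pattern = c("high", "medium", "low"),
                                          rows = 8L, cols = 12L) {
  stopifnot(all(c("low", "medium", "high") %in% names(doses)),
            all(pattern %in% names(doses)), cols >= 11)
  lev <- rep_len(pattern, 9)
  grid <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  wells <- dplyr::mutate(
    grid,
    well = well_name(.data$row, .data$col),
    role = dplyr::case_when(
      .data$col == 1 ~ "positive_control",
      .data$col >= 2 & .data$col <= 10 ~ "dose",
      .data$col == 11 ~ "negative_control",
      TRUE ~ "excluded"),
    condition = dplyr::case_when(
      .data$role == "positive_control" ~ "myr_minus",
      .data$role == "dose" ~ lev[pmax(.data$col - 1, 1)],
      .data$role == "negative_control" ~ "vehicle",
      TRUE ~ NA_character_),
    dose_uM = dplyr::case_when(
      .data$role == "dose" ~ unname(doses[lev[pmax(.data$col - 1, 1)]]),
      .data$role == "negative_control" ~ 0,
      TRUE ~ NA_real_))
  plate_layout(wells[, c("well", "row", "col", "condition", "dose_uM", "role")],
               rows, cols)
}

#' Read / write a plate layout as CSV
#'
#' @param path File path.
#' @param rows,cols Plate geometry (read only).
#' @return `read_plate_layout()` returns a [plate_layout()];
#'   `write_plate_layout()` returns `path` invisibly.
#' @export
read_plate_layout <- function(path, rows = 8L, cols = 12L) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_layout(wells, rows, cols)
}

#' @rdname read_plate_layout
#' @param layout A [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}
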