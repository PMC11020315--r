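# Zahnreihe segmentation, Z-spacing measurement and wave-direction
# classification.
#
# A Zahnreihe is a replacement wave: an ordered series of teeth along the
# jaw whose replacement indices decrease caudally (the most rostral member
# is the most mature). On the replacement-index graph each Zahnreihe is a
# degressive polyline; the horizontal distance between successive polylines,
# in tooth positions, is the Z-spacing.

#' Segment an ordered index series into Zahnreihen
#'
#' Partitions the series into maximal degressive runs: a new Zahnreihe
#' starts whenever the next point's index is greater than or equal to the
#' previous point's index, or whenever the position fails to increase
#' strictly (two generations in one alveolus belong to successive waves).
#' Every point belongs to exactly one Zahnreihe and concatenating the
#' Zahnreihen in order reproduces the series.
#'
#' @param series An ordered series of plotted teeth: a tibble with
#'   `position` and `replacement_index` columns, e.g. from
#'   [family_series()] (one point per alveolus, the usual input for
#'   Z-spacing) or [build_plot_series()]. If specimen/element/side columns
#'   are present, segmentation restarts within each such group.
#' @return The series with an integer `zahnreihe_id` column (1-based, in
#'   series order within each dentition row).
#' @examples
#' s <- tibble::tibble(position = 1:6,
#'                     replacement_index = c(1.8, 1.4, 1.0, 1.9, 1.5, 1.1))
#' segment_zahnreihen(s)$zahnreihe_id
#' @export
segment_zahnreihen <- function(series) {
  if (nrow(series) == 0) {
    return(mutate(series, zahnreihe_id = integer(0)))
  }
  group_cols <- intersect(c("specimen_id", "element", "side"), names(series))
  series |>
    group_by(across(dplyr::all_of(group_cols))) |>
    mutate(zahnreihe_id = segment_runs(.data$position,
                                       .data$replacement_index)) |>
    ungroup()
}

# run decomposition: id increments when index stops strictly decreasing or
# position stops strictly increasing
segment_runs <- function(position, index) {
  n <- length(position)
  if (n == 0) return(integer(0))
  breaks <- c(FALSE, diff(index) >= 0 | diff(position) <= 0)
  cumsum(breaks) + 1L
}

#' Measure Z-spacing between successive Zahnreihen
#'
#' Each Zahnreihe is treated as a polyline in (position, index) space. For
#' every member tooth of every Zahnreihe except the last, the measurement is
#' the horizontal (position-axis) distance from that tooth to the next
#' Zahnreihe's polyline evaluated at the same index value by linear
#' interpolation. Teeth whose index lies outside the next polyline's index
#' range contribute no measurement (no extrapolation). The mean of all
#' measurements is the dentition row's Z-spacing.
#'
#' @param segmented Output of [segment_zahnreihen()] for a single dentition
#'   row (one specimen/element/side).
#' @param tol Tolerance around 2.0 for calling the direction "alternating"
#'   (default 0: exactly 2.0).
#' @return A one-row tibble of class `"z_spacing_result"`: `n_zahnreihen`,
#'   `n_measurements`, `measurements` (list column), `mean_z` (unrounded),
#'   and `direction`.
#' @export
measure_z_spacing <- function(segmented, tol = 0) {
  zr_ids <- unique(segmented$zahnreihe_id)
  if (length(zr_ids) < 2) {
    zr_abort(
      "Z-spacing is undefined with fewer than 2 Zahnreihen",
      "zr_error_undefined_spacing"
    )
  }
  polylines <- split(segmented, segmented$zahnreihe_id)
  polylines <- polylines[order(as.integer(names(polylines)))]
  measurements <- numeric(0)
  for (i in seq_len(length(polylines) - 1)) {
    cur <- polylines[[i]]
    nxt <- polylines[[i + 1]]
    lo <- min(nxt$replacement_index)
    hi <- max(nxt$replacement_index)
    for (j in seq_len(nrow(cur))) {
      y <- cur$replacement_index[j]
      if (y < lo || y > hi) next
      x_next <- interp_position(nxt, y)
      measurements <- c(measurements, x_next - cur$position[j])
    }
  }
  nonpos <- measurements <= 0
  if (any(nonpos)) {
    warn(paste0("dropping ", sum(nonpos),
                " non-positive Z-spacing measurement(s)"))
    measurements <- measurements[!nonpos]
  }
  mean_z <- if (length(measurements) > 0) mean(measurements) else NA_real_
  tibble(
    n_zahnreihen = length(polylines),
    n_measurements = length(measurements),
    measurements = list(measurements),
    mean_z = mean_z,
    direction = if (is.na(mean_z)) NA_character_ else
      classify_direction(mean_z, tol)
  ) |>
    structure(class = c("z_spacing_result", class(tibble())))
}

# position of a Zahnreihe polyline at index level y (indices strictly
# decreasing along the polyline, so the mapping is single-valued)
interp_position <- function(poly, y) {
  if (nrow(poly) == 1) return(poly$position[1])
  # indices decrease along the polyline; approx() needs ascending x
  approx(x = rev(poly$replacement_index), y = rev(poly$position), xout = y,
         ties = "ordered")$y
}

#' Classify the replacement-wave direction from a Z-spacing value
#'
#' A Z-spacing above 2.0 indicates a replacement wave running rostral to
#' caudal, below 2.0 a caudal-to-rostral wave, and exactly 2.0 (within
#' `tol`) simple alternation between odd- and even-numbered positions.
#'
#' @param mean_z Positive Z-spacing value(s), in tooth positions.
#' @param tol Half-width of the "alternating" band around 2.0 (default 0).
#' @return Character vector: `"rostral_to_caudal"`, `"alternating"`, or
#'   `"caudal_to_rostral"`.
#' @examples
#' classify_direction(c(2.53, 2.0, 1.40))
#' @export
classify_direction <- function(mean_z, tol = 0) {
  if (any(is.na(mean_z)) || any(mean_z <= 0)) {
    zr_abort("mean_z must be positive", "zr_error_domain")
  }
  dplyr::case_when(
    abs(mean_z - 2.0) <= tol ~ "alternating",
    mean_z - 2.0 > tol ~ "rostral_to_caudal",
    TRUE ~ "caudal_to_rostral"
  )
}

#' Z-spacing for every dentition row of a tooth table
#'
#' Full pipeline per (specimen, element, side): replacement indices
#' ([replacement_index()]), per-family maturity series ([family_series()]),
#' Zahnreihe segmentation, and Z-spacing measurement. Rows with fewer than
#' two Zahnreihen get `NA` (an empty cell, not a failure).
#'
#' @param teeth A tooth table.
#' @param tol Tolerance passed to [classify_direction()].
#' @return A tibble with one row per dentition row: `specimen_id`,
#'   `element`, `side`, `n_zahnreihen`, `n_measurements`, `mean_z`
#'   (unrounded), `z_spacing` (rounded half-up to 2 decimals), `direction`.
#' @export
z_spacing <- function(teeth, tol = 0) {
  indexed <- replacement_index(teeth)
  series <- family_series(indexed)
  segmented <- segment_zahnreihen(series)
  segmented |>
    group_by(.data$specimen_id, .data$element, .data$side) |>
    group_modify(function(g, key) {
      res <- tryCatch(
        measure_z_spacing(g, tol = tol),
        zr_error_undefined_spacing = function(e) tibble(
          n_zahnreihen = length(unique(g$zahnreihe_id)),
          n_measurements = 0L,
          measurements = list(numeric(0)),
          mean_z = NA_real_,
          direction = NA_character_
        )
      )
      res
    }) |>
    ungroup() |>
    mutate(z_spacing = round_half_up(.data$mean_z, 2), .after = "mean_z")
}

#' Summarise Z-spacing across specimens and jaw elements
#'
#' Produces the published-table layout: one row per specimen with one value
#' per (element, side) rounded half-up to 2 decimals, plus per-element grand
#' means across specimens and sides. Because published grand means appear at
#' mixed precision, the element means are reported unrounded and at 2 and 3
#' decimals.
#'
#' @param x Either a tooth table (Z-spacings are computed via
#'   [z_spacing()]), or an already-summarised per-side table with columns
#'   `specimen_id`, `element`, `side` and `z_spacing` (or `mean_z`), e.g. a
#'   transcription of published per-side values.
#' @param tol Tolerance passed to [classify_direction()] when computing.
#' @return A list of class `"jaw_summary"` with components
#'   `by_specimen` (wide tibble, columns `<element>_<side>`) and
#'   `element_means` (tibble with `element`, `n_values`, `grand_mean`,
#'   `grand_mean_2dp`, `grand_mean_3dp`).
#' @export
summarize_jaw <- function(x, tol = 0) {
  per_side <- if (all(c("z_spacing", "element", "side") %in% names(x)) ||
                  all(c("mean_z", "element", "side") %in% names(x))) {
    y <- as_tibble(x)
    if (!"z_spacing" %in% names(y)) {
      y$z_spacing <- round_half_up(y$mean_z, 2)
    }
    y
  } else {
    z_spacing(x, tol = tol)
  }
  per_side <- per_side |>
    mutate(element = factor(.data$element, levels = zr_elements),
           side = factor(.data$side, levels = zr_sides))

  by_specimen <- per_side |>
    select("specimen_id", "element", "side", "z_spacing") |>
    mutate(z_spacing = round_half_up(.data$z_spacing, 2)) |>
    tidyr::pivot_wider(
      names_from = c("element", "side"),
      values_from = "z_spacing",
      names_sort = TRUE
    )

  element_means <- per_side |>
    filter(!is.na(.data$z_spacing)) |>
    group_by(.data$element) |>
    summarise(
      n_values = dplyr::n(),
      grand_mean = mean(round_half_up(.data$z_spacing, 2)),
      .groups = "drop"
    ) |>
    mutate(
      grand_mean_2dp = round_half_up(.data$grand_mean, 2),
      grand_mean_3dp = round_half_up(.data$grand_mean, 3),
      element = as.character(.data$element)
    )

  structure(
    list(by_specimen = by_specimen, element_means = element_means,
         per_side = per_side),
    class = "jaw_summary"
  )
}

#' @export
print.jaw_summary <- function(x, ...) {
  cat("Z-spacing summary\n\nPer specimen (tooth positions):\n")
  print(x$by_specimen)
  cat("\nPer-element grand means:\n")
  print(x$element_means)
  invisible(x)
}

#' @describeIn summarize_jaw Long per-side tidy view of a jaw summary.
#' @param ... Unused.
#' @export
tidy.jaw_summary <- function(x, ...) {
  x$per_side |>
    mutate(element = as.character(.data$element),
           side = as.character(.data$side)) |>
    select(dplyr::any_of(c("specimen_id", "element", "side", "n_zahnreihen",
                           "n_measurements", "mean_z", "z_spacing",
                           "direction")))
}
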