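# Odontochronology from von Ebner incremental lines: daily light/dark
# couplets in dentine. Counting couplets gives tooth formation time in
# days; their widths give the daily dentine apposition rate (DDAR).

#' Read a von Ebner increment-width table
#'
#' One row per daily couplet: `tooth_id`, `specimen_id`, `day_index`
#' (1-based, pulp-ward order), `width_um` (> 0), `section_plane`
#' (`coronal` or `mesiodistal`).
#'
#' @param path Delimited text file (comma or tab auto-detected).
#' @param delim Optional explicit delimiter.
#' @return A tibble of class `"increment_table"`, sorted by tooth and day.
#' @export
read_increment_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    zr_abort(paste0("increment table not found: ", path), "zr_error_io")
  }
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_increment_table(df)
}

#' Validate a data frame as an increment table
#'
#' @param df Data frame with columns `tooth_id`, `specimen_id`,
#'   `day_index`, `width_um`, `section_plane`.
#' @return A tibble of class `"increment_table"`.
#' @export
as_increment_table <- function(df) {
  df <- as_tibble(df)
  required <- c("tooth_id", "specimen_id", "day_index", "width_um",
                "section_plane")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    zr_abort(paste0("increment table is missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "zr_error_format")
  }
  check_enum(df$section_plane, c("coronal", "mesiodistal"), "section_plane")
  bad <- which(is.na(df$width_um) | df$width_um <= 0)
  if (length(bad) > 0) {
    zr_abort(paste0("width_um must be > 0; offending row(s): ",
                    paste(bad, collapse = ", ")),
             "zr_error_validation")
  }
  out <- df |>
    arrange(.data$specimen_id, .data$tooth_id, .data$day_index)
  class(out) <- c("increment_table", class(out))
  out
}

#' Tooth formation time from an increment series
#'
#' The number of daily von Ebner couplets recorded in a tooth equals the
#' number of days the tooth took to form.
#'
#' @param x A numeric vector of couplet widths, or an increment table (the
#'   count is computed per tooth).
#' @return Integer day count, or a tibble (`specimen_id`, `tooth_id`,
#'   `formation_days`) for a table input.
#' @examples
#' formation_time(rep(12, 46))
#' @export
formation_time <- function(x) {
  if (is.numeric(x)) {
    if (length(x) == 0) {
      zr_abort("empty increment series", "zr_error_validation")
    }
    return(length(x))
  }
  if (nrow(x) == 0) {
    zr_abort("empty increment series", "zr_error_validation")
  }
  x |>
    group_by(.data$specimen_id, .data$tooth_id) |>
    summarise(formation_days = dplyr::n(), .groups = "drop")
}

#' Daily dentine apposition rate (DDAR)
#'
#' The unweighted arithmetic mean couplet width, in micrometres per day.
#'
#' @inheritParams formation_time
#' @return Numeric mean width, or a tibble with a `ddar_um` column for a
#'   table input.
#' @examples
#' daily_apposition_rate(c(10, 14))
#' @export
daily_apposition_rate <- function(x) {
  if (is.numeric(x)) {
    if (length(x) == 0) {
      zr_abort("empty increment series", "zr_error_validation")
    }
    return(mean(x))
  }
  if (nrow(x) == 0) {
    zr_abort("empty increment series", "zr_error_validation")
  }
  x |>
    group_by(.data$specimen_id, .data$tooth_id) |>
    summarise(ddar_um = mean(.data$width_um), .groups = "drop")
}

#' Per-tooth histology summary
#'
#' Formation time, DDAR and total dentine thickness per sectioned tooth,
#' shaped like a published odontochronology table. `formation_days * ddar_um`
#' equals `total_thickness_um` exactly.
#'
#' @param x An increment table.
#' @return A tibble: `specimen_id`, `tooth_id`, `section_plane`,
#'   `formation_days`, `ddar_um` (unrounded), `ddar_um_4dp`,
#'   `total_thickness_um`.
#' @export
increment_summary <- function(x) {
  if (nrow(x) == 0) {
    zr_abort("empty increment series", "zr_error_validation")
  }
  x |>
    group_by(.data$specimen_id, .data$tooth_id, .data$section_plane) |>
    summarise(
      formation_days = dplyr::n(),
      ddar_um = mean(.data$width_um),
      total_thickness_um = sum(.data$width_um),
      .groups = "drop"
    ) |>
    mutate(ddar_um_4dp = round_half_up(.data$ddar_um, 4),
           .after = "ddar_um")
}

#' Infer a tooth replacement rate from a newly erupted tooth
#'
#' When a sectioned tooth is newly erupted and its family holds no (or only
#' an incipient) replacement tooth, the next generation has at most just
#' started forming, so the replacement rate is the same as, or slightly
#' less than, the tooth's formation time. The returned figure is that upper
#' bound, qualified as such. Any other configuration is not inferable this
#' way; use [rate_from_family()] with two successive-generation increment
#' counts instead.
#'
#' @param formation_days Formation time(s) in days (>= 1).
#' @param newly_erupted Logical: is the sectioned tooth newly erupted?
#' @param family_has_replacement Logical: does its family already hold a
#'   (non-incipient) replacement tooth?
#' @return A tibble with `formation_days`, `replacement_rate_days` and
#'   `rate_qualifier` (`"upper_bound_newly_erupted"`).
#' @examples
#' infer_replacement_rate(46, newly_erupted = TRUE,
#'                        family_has_replacement = FALSE)
#' @export
infer_replacement_rate <- function(formation_days, newly_erupted,
                                   family_has_replacement) {
  if (any(is.na(formation_days)) || any(formation_days < 1)) {
    zr_abort("formation_days must be >= 1", "zr_error_validation")
  }
  args <- vctrs_recycle(formation_days, newly_erupted,
                        family_has_replacement)
  if (any(!args$newly_erupted | args$family_has_replacement)) {
    zr_abort(
      paste0("replacement rate is only inferable from a newly erupted ",
             "tooth whose family has no replacement tooth; use ",
             "rate_from_family() with two successive-generation increment ",
             "counts instead"),
      "zr_error_not_inferable"
    )
  }
  tibble(
    formation_days = as.integer(args$formation_days),
    replacement_rate_days = as.integer(args$formation_days),
    rate_qualifier = "upper_bound_newly_erupted"
  )
}

# minimal common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(formation_days, newly_erupted,
                          family_has_replacement) {
  n <- max(length(formation_days), length(newly_erupted),
           length(family_has_replacement))
  list(
    formation_days = rep_len(formation_days, n),
    newly_erupted = rep_len(newly_erupted, n),
    family_has_replacement = rep_len(family_has_replacement, n)
  )
}

#' Replacement rate from two generations of one tooth family
#'
#' The exact tooth replacement rate is the difference in recorded formation
#' days between the older and the younger tooth of the same family: both
#' started forming one replacement cycle apart.
#'
#' @param older_days Increment count of the older-generation tooth.
#' @param younger_days Increment count of the younger-generation tooth
#'   (0 when replacement has only just initiated).
#' @return A tibble with `replacement_rate_days` and `rate_qualifier`
#'   (`"exact_family_difference"`).
#' @examples
#' rate_from_family(50, 20)
#' @export
rate_from_family <- function(older_days, younger_days) {
  n <- max(length(older_days), length(younger_days))
  older_days <- rep_len(older_days, n)
  younger_days <- rep_len(younger_days, n)
  if (any(is.na(older_days)) || any(is.na(younger_days)) ||
      any(younger_days < 0)) {
    zr_abort("increment counts must be non-negative", "zr_error_validation")
  }
  if (any(younger_days >= older_days)) {
    zr_abort(
      "the older tooth must record strictly more days than the younger",
      "zr_error_ordering"
    )
  }
  tibble(
    replacement_rate_days = as.integer(older_days - younger_days),
    rate_qualifier = "exact_family_difference"
  )
}
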