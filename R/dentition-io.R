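# Reading, validation and writing of per-tooth measurement tables.
#
# A tooth table is a tibble with one row per tooth (functional or
# replacement generation) and columns:
#   specimen_id, element, side, position, tooth_class, generation,
#   total_length_mm, flags (optional), skull_length_mm (optional),
#   growth_stage (optional)
# Row order never carries meaning; ordering always comes from `position`.

zr_required_cols <- c(
  "specimen_id", "element", "side", "position",
  "tooth_class", "generation", "total_length_mm"
)

#' Read a tooth-measurement table
#'
#' Reads a delimited text file of per-tooth measurements into a validated
#' tooth table. One row describes one tooth: a functional tooth
#' (`generation` 0) or a replacement tooth (`generation` >= 1) of one tooth
#' family (alveolus) on one jaw element and side. `total_length_mm` is the
#' total tooth length in mm and may be empty for germs too small to measure;
#' such teeth still count but are excluded from index computation.
#'
#' The delimiter is auto-detected among comma and tab unless given. Unknown
#' columns are preserved. Left and right sides are independent dentition
#' rows; positions are 1-based and numbered rostral to caudal.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects `","` vs
#'   `"\t"` from the header line.
#' @return A validated tooth table (tibble, class `"tooth_table"`), sorted
#'   by specimen, element, side, position, tooth class and generation.
#' @seealso [as_tooth_table()] to validate an in-memory data frame,
#'   [write_tooth_table()] for the inverse operation.
#' @export
read_tooth_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    zr_abort(paste0("tooth table not found: ", path), "zr_error_io")
  }
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  as_tooth_table(df)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Validate a data frame as a tooth table
#'
#' Checks column presence, enum values, positivity of lengths, duplicate
#' (position, class, generation) records and orphan replacement teeth, then
#' returns the table in canonical order so that results never depend on
#' input row order.
#'
#' @param df A data frame of tooth records (see [read_tooth_table()] for the
#'   column contract).
#' @return A tibble of class `"tooth_table"`.
#' @export
as_tooth_table <- function(df) {
  df <- as_tibble(df)
  missing_cols <- setdiff(zr_required_cols, names(df))
  if (length(missing_cols) > 0) {
    zr_abort(
      paste0("tooth table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "zr_error_format"
    )
  }
  if (!"flags" %in% names(df)) df$flags <- NA_character_
  df$flags <- as.character(df$flags)
  df$specimen_id <- as.character(df$specimen_id)
  df$position <- as.integer(df$position)
  df$generation <- as.integer(df$generation)
  df$total_length_mm <- as.numeric(df$total_length_mm)

  check_enum(df$element, zr_elements, "element")
  check_enum(df$side, zr_sides, "side")
  check_enum(df$tooth_class, zr_classes, "tooth_class")
  if ("growth_stage" %in% names(df)) {
    check_enum(df$growth_stage[!is.na(df$growth_stage)], zr_stages,
               "growth_stage")
  }
  bad_flag <- df$flags[!is.na(df$flags)] |>
    lapply(parse_flags) |> unlist() |> setdiff(zr_flags)
  if (length(bad_flag) > 0) {
    zr_abort(paste0("unknown flag value(s): ",
                    paste(unique(bad_flag), collapse = ", ")),
             "zr_error_validation")
  }

  bad_len <- which(!is.na(df$total_length_mm) & df$total_length_mm <= 0)
  if (length(bad_len) > 0) {
    zr_abort(
      paste0("total_length_mm must be > 0; offending row(s): ",
             paste(bad_len, collapse = ", ")),
      "zr_error_validation"
    )
  }
  bad_pos <- which(is.na(df$position) | df$position < 1L)
  if (length(bad_pos) > 0) {
    zr_abort(paste0("position must be an integer >= 1; offending row(s): ",
                    paste(bad_pos, collapse = ", ")),
             "zr_error_validation")
  }
  bad_gen <- which(
    is.na(df$generation) |
      (df$tooth_class == "functional" & df$generation != 0L) |
      (df$tooth_class == "replacement" & df$generation < 1L)
  )
  if (length(bad_gen) > 0) {
    zr_abort(
      paste0("generation must be 0 for functional teeth and >= 1 for ",
             "replacement teeth; offending row(s): ",
             paste(bad_gen, collapse = ", ")),
      "zr_error_validation"
    )
  }
  if ("skull_length_mm" %in% names(df)) {
    bad_skull <- which(!is.na(df$skull_length_mm) & df$skull_length_mm <= 0)
    if (length(bad_skull) > 0) {
      zr_abort(paste0("skull_length_mm must be > 0; offending row(s): ",
                      paste(bad_skull, collapse = ", ")),
               "zr_error_validation")
    }
  }

  dup <- df |>
    count(.data$specimen_id, .data$element, .data$side, .data$position,
          .data$tooth_class, .data$generation) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    zr_abort(
      paste0("duplicate tooth record(s) for (specimen, element, side, ",
             "position, tooth_class, generation): ",
             paste(dup$specimen_id, dup$element, dup$side, dup$position,
                   sep = "/", collapse = "; ")),
      "zr_error_validation"
    )
  }

  # every replacement tooth needs a functional tooth at its position, or an
  # explicit empty_alveolus flag
  orphans <- df |>
    group_by(.data$specimen_id, .data$element, .data$side, .data$position) |>
    filter(!any(.data$tooth_class == "functional"),
           any(.data$tooth_class == "replacement"),
           !any(has_flag(.data$flags, "empty_alveolus"))) |>
    ungroup() |>
    distinct(.data$specimen_id, .data$element, .data$side, .data$position)
  if (nrow(orphans) > 0) {
    zr_abort(
      paste0("replacement tooth without a functional tooth and without an ",
             "empty_alveolus flag at: ",
             paste(orphans$specimen_id, orphans$element, orphans$side,
                   orphans$position, sep = "/", collapse = "; ")),
      "zr_error_validation"
    )
  }

  out <- df |>
    arrange(.data$specimen_id, .data$element, .data$side, .data$position,
            .data$tooth_class, .data$generation)
  class(out) <- c("tooth_table", class(out))
  out
}

check_enum <- function(x, allowed, name) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    zr_abort(
      paste0("invalid ", name, " value(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(allowed, collapse = ", "), ")"),
      "zr_error_validation"
    )
  }
  invisible(x)
}

#' Write a tooth table back to delimited text
#'
#' @param x A tooth table.
#' @param path Output file path (`.csv` or `.tsv` chooses the delimiter).
#' @return `path`, invisibly.
#' @export
write_tooth_table <- function(x, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

#' Write analysis products and a run manifest
#'
#' Writes each named product as one CSV file under `path` plus a
#' `manifest.json` recording the file list, a hash of the configuration,
#' the seed, and the package version. Identical products written with the
#' same configuration and seed produce byte-identical files.
#'
#' @param results Named list of data frames (non-empty).
#' @param path Output directory; created if missing.
#' @param seed Integer seed used for the run (recorded in the manifest).
#' @param config Optional configuration list; a stable hash is recorded.
#' @return The manifest, invisibly (a list).
#' @export
write_results <- function(results, path, seed = NULL, config = NULL) {
  if (!is.list(results) || length(results) == 0 ||
      is.null(names(results)) || any(!nzchar(names(results)))) {
    zr_abort("`results` must be a non-empty named list of data frames",
             "zr_error_validation")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || !dir.exists(path)) {
    zr_abort(paste0("cannot create output directory: ", path), "zr_error_io")
  }
  files <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) {
      zr_abort(paste0("result `", nm, "` is not a data frame"),
               "zr_error_validation")
    }
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(df, f, na = "")
    files <- c(files, basename(f))
  }
  manifest <- list(
    files = files,
    seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("zahnreihen"))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
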