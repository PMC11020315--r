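# Per-specimen dentition counts and cross-ontogeny trends.

#' Count a specimen's dentition
#'
#' Exact counts per (specimen, element, side): alveoli (distinct positions
#' with any record), functional teeth, first- and later-generation
#' replacement teeth, remnants of resorbed teeth (from the
#' `remnant_present` flag), and the replacement:functional ratio.
#'
#' @param teeth A tooth table.
#' @param specimens Optional tibble with a `specimen_id` column (and
#'   optionally `element`, `side`): rows to force into the output even when
#'   no teeth are recorded (all-zero counts).
#' @return An ontogeny table: one row per (specimen, element, side) with
#'   `n_alveoli`, `n_functional`, `n_replacement_gen1`,
#'   `n_replacement_gen2plus`, `n_remnants`, `replacement_ratio` (to 3
#'   decimals, `NA` when no functional teeth).
#' @export
count_dentition <- function(teeth, specimens = NULL) {
  counts <- teeth |>
    group_by(.data$specimen_id, .data$element, .data$side) |>
    summarise(
      n_alveoli = dplyr::n_distinct(.data$position),
      n_functional = sum(.data$tooth_class == "functional"),
      n_replacement_gen1 = sum(.data$tooth_class == "replacement" &
                                 .data$generation == 1L),
      n_replacement_gen2plus = sum(.data$tooth_class == "replacement" &
                                     .data$generation >= 2L),
      n_remnants = sum(has_flag(.data$flags, "remnant_present")),
      .groups = "drop"
    )
  if (!is.null(specimens)) {
    missing_rows <- specimens |>
      as_tibble() |>
      distinct() |>
      anti_join(counts,
                by = intersect(names(specimens),
                               c("specimen_id", "element", "side")))
    if (nrow(missing_rows) > 0) {
      if (!"element" %in% names(missing_rows)) {
        missing_rows$element <- NA_character_
      }
      if (!"side" %in% names(missing_rows)) missing_rows$side <- NA_character_
      zero <- missing_rows |>
        mutate(n_alveoli = 0L, n_functional = 0L, n_replacement_gen1 = 0L,
               n_replacement_gen2plus = 0L, n_remnants = 0L)
      counts <- bind_rows(counts, zero)
    }
  }
  counts |>
    mutate(replacement_ratio = replacement_ratio(
      .data$n_replacement_gen1 + .data$n_replacement_gen2plus,
      .data$n_functional
    )) |>
    arrange(.data$specimen_id, .data$element, .data$side)
}

#' Replacement:functional tooth ratio
#'
#' @param n_replacement Total replacement teeth (all generations).
#' @param n_functional Functional tooth count; a ratio is undefined (`NA`)
#'   when zero.
#' @return Numeric ratio rounded half-up to 3 decimals.
#' @examples
#' replacement_ratio(13, 15)
#' @export
replacement_ratio <- function(n_replacement, n_functional) {
  if (any(n_replacement < 0, na.rm = TRUE) ||
      any(n_functional < 0, na.rm = TRUE)) {
    zr_abort("counts must be non-negative", "zr_error_validation")
  }
  ifelse(n_functional > 0,
         round_half_up(n_replacement / n_functional, 3),
         NA_real_)
}

#' Ontogenetic trend of dentition counts
#'
#' Orders specimens by growth stage (early juvenile, late juvenile,
#' subadult), ties broken by skull length, then reports each count metric
#' as a sequence in that order together with a monotonicity verdict. No
#' statistical test is applied: with a handful of fossil specimens the
#' verdict is descriptive.
#'
#' @param counts An ontogeny table from [count_dentition()].
#' @param specimens A tibble with `specimen_id`, `growth_stage` and
#'   optionally `skull_length_mm`, used only for ordering.
#' @param metrics Count columns to report (default: all count columns).
#' @return A tibble of class `"ontogeny_trend"`: `metric`, `specimens`
#'   (list), `values` (list, summed over elements and sides per specimen),
#'   `verdict` (`"non_decreasing"`, `"non_increasing"`, `"flat"`, or
#'   `"mixed"`).
#' @export
ontogenetic_trend <- function(counts, specimens,
                              metrics = c("n_alveoli", "n_functional",
                                          "n_replacement_gen1",
                                          "n_replacement_gen2plus",
                                          "n_remnants")) {
  specimens <- as_tibble(specimens)
  if (nrow(specimens) < 2) {
    zr_abort("an ontogenetic trend needs at least 2 specimens",
             "zr_error_validation")
  }
  if (!"skull_length_mm" %in% names(specimens)) {
    specimens$skull_length_mm <- NA_real_
  }
  stage_rank <- match(specimens$growth_stage,
                      c("early_juvenile", "late_juvenile", "subadult"))
  unordered <- is.na(stage_rank) & is.na(specimens$skull_length_mm)
  if (any(unordered)) {
    zr_abort(
      paste0("specimen(s) cannot be ordered (no growth stage, no skull ",
             "length): ",
             paste(specimens$specimen_id[unordered], collapse = ", ")),
      "zr_error_ordering"
    )
  }
  ord <- order(stage_rank, specimens$skull_length_mm, na.last = TRUE)
  specimen_order <- specimens$specimen_id[ord]

  per_specimen <- counts |>
    group_by(.data$specimen_id) |>
    summarise(across(dplyr::all_of(metrics), sum), .groups = "drop")
  per_specimen <- per_specimen[
    match(specimen_order, per_specimen$specimen_id), , drop = FALSE]
  per_specimen <- per_specimen[!is.na(per_specimen$specimen_id), ,
                               drop = FALSE]

  out <- purrr::map_dfr(metrics, function(m) {
    v <- per_specimen[[m]]
    tibble(
      metric = m,
      specimens = list(per_specimen$specimen_id),
      values = list(v),
      verdict = trend_verdict(v)
    )
  })
  class(out) <- c("ontogeny_trend", class(out))
  out
}

trend_verdict <- function(v) {
  nd <- all(diff(v) >= 0)
  ni <- all(diff(v) <= 0)
  if (nd && ni) "flat"
  else if (nd) "non_decreasing"
  else if (ni) "non_increasing"
  else "mixed"
}

#' @export
print.ontogeny_trend <- function(x, ...) {
  cat("Ontogenetic trend (specimens in ontogenetic order):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s %s  [%s]\n", x$metric[i],
                paste(x$values[[i]], collapse = ", "), x$verdict[i]))
  }
  invisible(x)
}
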