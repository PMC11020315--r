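# Replacement indices sensu Fastnacht: a dimensionless maturity score per
# tooth that is comparable across positions despite varying tooth size.

#' Compute replacement indices for every tooth family
#'
#' A replacement tooth's index is its total length divided by the total
#' length of the corresponding functional tooth, so it lies in (0, 1) for a
#' germ smaller than its predecessor (values above 1 are kept but flagged).
#' The functional tooth then carries 1.0 plus the index of its most mature
#' measurable replacement, or exactly 1.0 when it has none. The functional
#' index therefore summarises the replacement state of the whole family.
#'
#' Families whose functional tooth has no measurable length are excluded
#' with a warning; replacement teeth without a measurable length are skipped
#' with a warning but do not exclude their family.
#'
#' @param teeth A tooth table ([as_tooth_table()]); any subset of rows works
#'   as long as families are complete.
#' @return A tibble with one row per measurable tooth: the identifying
#'   columns plus `replacement_index` and `index_over_one` (logical flag for
#'   replacement indices > 1).
#' @examples
#' fam <- as_tooth_table(tibble::tibble(
#'   specimen_id = "S1", element = "maxilla", side = "left",
#'   position = c(1L, 1L), tooth_class = c("functional", "replacement"),
#'   generation = c(0L, 1L), total_length_mm = c(10, 4)
#' ))
#' replacement_index(fam)
#' @export
replacement_index <- function(teeth) {
  grouped <- teeth |>
    group_by(.data$specimen_id, .data$element, .data$side, .data$position)

  # families excluded because the functional tooth is unmeasurable (or the
  # alveolus is empty): indices are undefined there
  excluded <- grouped |>
    filter(!any(.data$tooth_class == "functional" &
                  !is.na(.data$total_length_mm))) |>
    ungroup()
  if (nrow(excluded) > 0) {
    keys <- excluded |>
      distinct(.data$specimen_id, .data$element, .data$side, .data$position)
    warn(paste0(
      "excluding ", nrow(keys), " tooth famil",
      if (nrow(keys) == 1) "y" else "ies",
      " without a measurable functional tooth: ",
      paste(keys$specimen_id, keys$element, keys$side, keys$position,
            sep = "/", collapse = "; ")
    ))
  }

  n_unmeasurable <- sum(teeth$tooth_class == "replacement" &
                          is.na(teeth$total_length_mm))
  if (n_unmeasurable > 0) {
    warn(paste0("skipping ", n_unmeasurable,
                " replacement tooth/teeth without a measurable length"))
  }

  out <- grouped |>
    filter(any(.data$tooth_class == "functional" &
                 !is.na(.data$total_length_mm))) |>
    mutate(
      functional_length = .data$total_length_mm[
        .data$tooth_class == "functional"][1],
      replacement_index = dplyr::case_when(
        .data$tooth_class == "replacement" ~
          .data$total_length_mm / .data$functional_length,
        TRUE ~ NA_real_
      )
    ) |>
    mutate(
      replacement_index = ifelse(
        .data$tooth_class == "functional",
        1 + max(c(0, .data$replacement_index[
          .data$tooth_class == "replacement" &
            !is.na(.data$replacement_index)])),
        .data$replacement_index
      )
    ) |>
    ungroup() |>
    filter(!is.na(.data$replacement_index)) |>
    mutate(index_over_one = .data$tooth_class == "replacement" &
             .data$replacement_index > 1) |>
    select(-"functional_length")
  if (any(out$index_over_one)) {
    warn("replacement index > 1 for some teeth (replacement longer than its functional tooth)")
  }
  out
}

#' Arrange indexed teeth into plot order
#'
#' Orders the points of the replacement-index graph (y = replacement index,
#' x = tooth position): position ascending, and within one position the
#' functional point first, then replacement points by descending index.
#' This is the full point set drawn on a Zahnreihen graph.
#'
#' @param indexed Output of [replacement_index()] (one or more dentition
#'   rows; the ordering is applied within each specimen/element/side).
#' @return The same tibble ordered for plotting, with class `"zr_series"`.
#' @export
build_plot_series <- function(indexed) {
  out <- indexed |>
    mutate(.class_rank = match(.data$tooth_class, zr_classes)) |>
    arrange(.data$specimen_id, .data$element, .data$side, .data$position,
            .data$.class_rank, desc(.data$replacement_index)) |>
    select(-".class_rank")
  class(out) <- unique(c("zr_series", class(out)))
  out
}

#' Reduce a dentition row to its per-family maturity series
#'
#' One point per alveolus: the functional tooth's replacement index (1 plus
#' the most mature replacement's index). Because the functional index
#' encodes the family's whole replacement state, this series carries the
#' degressive wave signal that Zahnreihe segmentation operates on, without
#' the vertical duplication that functional + replacement point pairs would
#' introduce at each position.
#'
#' @inheritParams build_plot_series
#' @return Ordered tibble (class `"zr_series"`) with one functional point
#'   per position.
#' @export
family_series <- function(indexed) {
  out <- indexed |>
    filter(.data$tooth_class == "functional") |>
    arrange(.data$specimen_id, .data$element, .data$side, .data$position)
  class(out) <- unique(c("zr_series", class(out)))
  out
}
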