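# Orchestration: one entry point running each analysis stage from a
# configuration list (or YAML/JSON file) and writing products plus a run
# manifest. The command-line wrapper in inst/cli/zahnreihen-cli.R is a
# thin shell over run_pipeline().

#' Read a pipeline configuration
#'
#' @param path YAML or JSON file of configuration fields (see
#'   [run_pipeline()]).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    zr_abort(paste0("config file not found: ", path), "zr_error_io")
  }
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run one analysis stage end to end
#'
#' Commands and the configuration fields they use:
#' \describe{
#'   \item{`zahnreihe`}{`teeth` (tooth table path), `tol_alternating`
#'     (default 0). Writes per-tooth Zahnreihe assignments, the per-side
#'     Z-spacing table, and the wide summary with element grand means.}
#'   \item{`rates`}{`increments` (increment table path). Writes the
#'     per-tooth histology summary (formation days, DDAR).}
#'   \item{`ontogeny`}{`teeth`. Writes dentition counts; adds the trend
#'     report when growth stages are present.}
#'   \item{`asr`}{`tree` (newick), `ages` (CSV: taxon, fad, lad),
#'     `states` (CSV: taxon, state), `root_extension` (default 1),
#'     `n_maps` (default 1000), `seed`. Writes the calibrated tree
#'     (newick), model comparison, and node-state posteriors.}
#'   \item{`simulate`}{`seed`, plus optional `period`, `n_positions`,
#'     `noise_cv`, `n_days`, `mean_width`, `cv`. Writes simulated input
#'     tables with provenance.}
#' }
#' All commands write their products with [write_results()] under
#' `config$out` (default `"."`). Runs with the same inputs and seed write
#' byte-identical tables.
#'
#' @param command One of `"zahnreihe"`, `"rates"`, `"ontogeny"`, `"asr"`,
#'   `"simulate"`.
#' @param config Named list, or path to a YAML/JSON file.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(command = c("zahnreihe", "rates", "ontogeny",
                                     "asr", "simulate"),
                         config = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out %||% "."
  seed <- config$seed %||% NULL

  results <- switch(
    command,
    zahnreihe = run_zahnreihe(config),
    rates = run_rates(config),
    ontogeny = run_ontogeny(config),
    asr = run_asr(config),
    simulate = run_simulate(config)
  )
  write_results(results, out_dir, seed = seed, config = config)
}

require_input <- function(config, field) {
  path <- config[[field]]
  if (is.null(path)) {
    zr_abort(paste0("config field `", field, "` is required"),
             "zr_error_config")
  }
  if (!file.exists(path)) {
    zr_abort(paste0("input file for `", field, "` not found: ", path),
             "zr_error_io")
  }
  path
}

run_zahnreihe <- function(config) {
  teeth <- read_tooth_table(require_input(config, "teeth"))
  tol <- config$tol_alternating %||% 0
  indexed <- replacement_index(teeth)
  assignments <- segment_zahnreihen(family_series(indexed))
  spacing <- z_spacing(teeth, tol = tol) |>
    select(-"measurements")
  summary <- summarize_jaw(spacing, tol = tol)
  plot_series <- build_plot_series(indexed) |>
    select(dplyr::any_of(c("specimen_id", "element", "side", "position",
                           "tooth_class", "generation",
                           "replacement_index")))
  list(
    zahnreihe_assignments = assignments,
    z_spacing_by_side = spacing,
    z_spacing_summary = summary$by_specimen,
    z_spacing_element_means = summary$element_means,
    plot_series = plot_series
  )
}

run_rates <- function(config) {
  inc <- read_increment_table(require_input(config, "increments"))
  summary <- increment_summary(inc)
  newly <- config$newly_erupted %||% TRUE
  rates <- tryCatch(
    bind_cols(
      summary |> select("specimen_id", "tooth_id", "section_plane"),
      infer_replacement_rate(summary$formation_days, newly,
                             config$family_has_replacement %||% FALSE)
    ),
    zr_error_not_inferable = function(e) NULL
  )
  out <- list(histology_summary = summary)
  if (!is.null(rates)) out$replacement_rates <- rates
  out
}

run_ontogeny <- function(config) {
  teeth <- read_tooth_table(require_input(config, "teeth"))
  counts <- count_dentition(teeth)
  out <- list(dentition_counts = counts)
  if ("growth_stage" %in% names(teeth) &&
      dplyr::n_distinct(teeth$specimen_id) >= 2) {
    specimens <- teeth |>
      distinct(.data$specimen_id,
               growth_stage = .data$growth_stage,
               skull_length_mm = if ("skull_length_mm" %in% names(teeth))
                 .data$skull_length_mm else NA_real_)
    trend <- ontogenetic_trend(counts, specimens)
    out$ontogenetic_trend <- trend |>
      mutate(specimens = purrr::map_chr(.data$specimens, paste,
                                        collapse = ";"),
             values = purrr::map_chr(.data$values, paste, collapse = ";"))
  }
  out
}

run_asr <- function(config) {
  tree <- as_phylo(require_input(config, "tree"))
  ages <- readr::read_csv(require_input(config, "ages"),
                          show_col_types = FALSE)
  states <- readr::read_csv(require_input(config, "states"),
                            show_col_types = FALSE)
  cal <- calibrate_equal(tree, ages,
                         root_extension = config$root_extension %||% 1)
  fits <- fit_mk_models(cal, states,
                        n_starts = config$n_starts %||% 5)
  asr <- model_averaged_maps(fits, total = config$n_maps %||% 1000,
                             seed = config$seed %||% NULL)
  newick_path <- file.path(config$out %||% ".", "calibrated_tree.nwk")
  ok <- dir.exists(dirname(newick_path)) ||
    dir.create(dirname(newick_path), recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(cal, newick_path)
  list(
    model_comparison = glance(fits),
    map_allocation = asr$allocation,
    node_posterior = asr$node_posterior,
    root_posterior = asr$root_posterior
  )
}

run_simulate <- function(config) {
  seed <- config$seed %||% 1
  dent <- simulate_dentition(
    n_positions = config$n_positions %||% 15,
    period = config$period %||% 2.5,
    noise_cv = config$noise_cv %||% 0.03,
    seed = seed
  )
  inc <- simulate_increments(
    n_days = config$n_days %||% 46,
    mean_width = config$mean_width %||% 11.7,
    cv = config$cv %||% 0.1,
    seed = seed + 1
  )
  list(
    simulated_teeth = dent,
    simulated_increments = inc,
    simulation_provenance = tibble(
      dataset = c("simulated_teeth", "simulated_increments"),
      provenance = c(jsonlite::toJSON(provenance(dent), auto_unbox = TRUE,
                                      digits = NA),
                     jsonlite::toJSON(provenance(inc), auto_unbox = TRUE,
                                      digits = NA))
    )
  )
}
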