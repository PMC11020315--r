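# Ground-truthed simulators for every pipeline stage. Each generator
# embeds its generating parameters in a `provenance` attribute; recovery
# tests read the truth only from there.

#' Simulate a dentition with a known replacement-wave period
#'
#' Builds one dentition row (functional tooth plus one replacement tooth
#' per alveolus) whose replacement indices follow a degressive sawtooth
#' wave: `RI(x) = 1 - frac((x - phase) / period)`, mapped onto (0, 1], so
#' the index decreases caudally within each wave and the true Z-spacing is
#' `period`. Replacement tooth lengths are `RI(x)` times the functional
#' length; multiplicative lognormal noise with coefficient of variation
#' `noise_cv` is applied to all lengths (mean-preserving).
#'
#' The default functional-length profile is unimodal with its maximum at
#' position 8, mimicking maxillary tooth rows whose crowns peak mid-row.
#'
#' @param n_positions Number of alveoli (>= 4; default 15).
#' @param period True wave period in tooth positions (> 1; default 2.5).
#' @param phase Wave phase offset in tooth positions.
#' @param functional_length_profile Optional numeric vector of per-position
#'   mean functional lengths in mm.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal length noise (>= 0, < 0.5; default 0).
#' @param seed Optional integer seed.
#' @param specimen_id,element,side Identity of the simulated dentition row.
#' @return A tooth table with a `provenance` attribute (list with `period`,
#'   `phase`, `noise_cv`, `seed`, `true_indices`).
#' @examples
#' d <- simulate_dentition(n_positions = 12, period = 3, noise_cv = 0)
#' z_spacing(d)$mean_z
#' @export
simulate_dentition <- function(n_positions = 15, period = 2.5, phase = 0,
                               functional_length_profile = NULL,
                               noise_cv = 0, seed = NULL,
                               specimen_id = "SIM1", element = "maxilla",
                               side = "left") {
  if (n_positions < 4) {
    zr_abort("n_positions must be >= 4", "zr_error_validation")
  }
  if (period <= 1) zr_abort("period must be > 1", "zr_error_validation")
  if (noise_cv < 0 || noise_cv >= 0.5) {
    zr_abort("noise_cv must be in [0, 0.5)", "zr_error_validation")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n_positions)
  ri <- 1 - frac((x - phase) / period)
  ri[ri == 0] <- 1                      # map onto (0, 1]

  profile <- functional_length_profile %||%
    (8 + 6 * exp(-((x - 8)^2) / 18))    # unimodal, peak at position 8, mm
  if (length(profile) != n_positions) {
    zr_abort("functional_length_profile must have n_positions entries",
             "zr_error_validation")
  }

  func_len <- profile * length_noise(n_positions, noise_cv)
  repl_len <- ri * profile * length_noise(n_positions, noise_cv)

  teeth <- bind_rows(
    tibble(specimen_id = specimen_id, element = element, side = side,
           position = x, tooth_class = "functional", generation = 0L,
           total_length_mm = func_len),
    tibble(specimen_id = specimen_id, element = element, side = side,
           position = x, tooth_class = "replacement", generation = 1L,
           total_length_mm = repl_len)
  )
  out <- as_tooth_table(teeth)
  attr(out, "provenance") <- list(
    generator = "simulate_dentition", period = period, phase = phase,
    noise_cv = noise_cv, seed = seed, true_indices = ri
  )
  out
}

# mean-preserving multiplicative lognormal noise factors
length_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a von Ebner increment series
#'
#' Daily couplet widths drawn lognormally around `mean_width` with the
#' given coefficient of variation; the formation time of the result is
#' `n_days` by construction.
#'
#' @param n_days Number of daily couplets (>= 1).
#' @param mean_width Mean couplet width in micrometres (> 0).
#' @param cv Coefficient of variation of the widths (>= 0).
#' @param seed Optional integer seed.
#' @param tooth_id,specimen_id,section_plane Identity of the series.
#' @return An increment table with a `provenance` attribute (`n_days`,
#'   `mean_width`, `cv`, `seed`).
#' @examples
#' s <- simulate_increments(46, mean_width = 11.7, cv = 0.1, seed = 1)
#' formation_time(s)
#' @export
simulate_increments <- function(n_days, mean_width, cv = 0, seed = NULL,
                                tooth_id = "SIMT1", specimen_id = "SIM1",
                                section_plane = "coronal") {
  if (n_days < 1) zr_abort("n_days must be >= 1", "zr_error_validation")
  if (mean_width <= 0) {
    zr_abort("mean_width must be > 0", "zr_error_validation")
  }
  if (cv < 0) zr_abort("cv must be >= 0", "zr_error_validation")
  if (!is.null(seed)) set.seed(seed)
  widths <- mean_width * length_noise(n_days, cv)
  out <- as_increment_table(tibble(
    tooth_id = tooth_id, specimen_id = specimen_id,
    day_index = seq_len(n_days), width_um = widths,
    section_plane = section_plane
  ))
  attr(out, "provenance") <- list(
    generator = "simulate_increments", n_days = n_days,
    mean_width = mean_width, cv = cv, seed = seed
  )
  out
}

#' Simulate a discrete character on a tree
#'
#' Evolves a k-state character from the root towards the tips under
#' generator `Q` with exponential waiting times, retaining the true
#' internal-node states for recovery tests.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param q Generator matrix.
#' @param state_levels State names matching the rows of `q`.
#' @param root_state Root state (name or index); if `NULL`, drawn from
#'   `root_prior`.
#' @param root_prior Used only when `root_state` is `NULL`: `"flat"`,
#'   `"stationary"`, or a probability vector.
#' @param seed Optional integer seed.
#' @return A tibble (`taxon`, `state`) with attributes `node_states`
#'   (true states for all nodes, named by node number) and `provenance`.
#' @export
simulate_mk_tips <- function(tree, q, state_levels = NULL,
                             root_state = NULL, root_prior = "flat",
                             seed = NULL) {
  check_generator(q)
  k <- nrow(q)
  state_levels <- state_levels %||% paste0("state", seq_len(k))
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_state <- integer(n_tip + tree$Nnode)
  if (is.null(root_state)) {
    node_state[root] <- sample.int(k, 1,
                                   prob = root_prior_vector(root_prior, q, k))
  } else {
    node_state[root] <- if (is.character(root_state)) {
      match(root_state, state_levels)
    } else {
      as.integer(root_state)
    }
    if (is.na(node_state[root]) || node_state[root] < 1 ||
        node_state[root] > k) {
      zr_abort("invalid root_state", "zr_error_validation")
    }
  }
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(post$edge)))) {       # preorder
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    path <- forward_path(node_state[p], post$edge.length[e], q)
    node_state[ch] <- path$states[length(path$states)]
  }
  out <- tibble(taxon = tree$tip.label,
                state = state_levels[node_state[seq_len(n_tip)]])
  attr(out, "node_states") <- setNames(state_levels[node_state],
                                       seq_along(node_state))
  attr(out, "provenance") <- list(
    generator = "simulate_mk_tips", q = q, state_levels = state_levels,
    root_state = state_levels[node_state[root]], seed = seed
  )
  out
}

#' Generating parameters of a simulated dataset
#'
#' @param x An object produced by one of the simulators.
#' @return The provenance list (generator name, parameters, seed).
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) {
    zr_abort("object carries no provenance", "zr_error_domain")
  }
  p
}
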