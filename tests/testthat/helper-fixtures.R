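# Shared in-code fixtures and independent oracles.

# a small hand-written dentition: 3 families, one replacement tooth
make_simple_teeth <- function() {
  as_tooth_table(tibble::tibble(
    specimen_id = "S1",
    element = "maxilla",
    side = "left",
    position = c(1L, 1L, 2L, 3L),
    tooth_class = c("functional", "replacement", "functional", "functional"),
    generation = c(0L, 1L, 0L, 0L),
    total_length_mm = c(10, 4, 9, 8)
  ))
}

# premaxilla in the style of an early-juvenile specimen: 5 alveoli,
# replacement teeth at positions 1, 3, 5
make_premax_teeth <- function() {
  as_tooth_table(tibble::tibble(
    specimen_id = "EJ1",
    element = "premaxilla",
    side = "right",
    position = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 5L),
    tooth_class = c("functional", "replacement", "functional", "functional",
                    "replacement", "functional", "functional",
                    "replacement"),
    generation = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L),
    total_length_mm = c(6.0, 4.8, 5.8, 6.2, 3.1, 6.0, 5.5, 1.1)
  ))
}

# independent run-decomposition oracle: brute-force scan deciding, for
# every adjacent pair, whether a boundary must fall between them
oracle_runs <- function(position, index) {
  id <- integer(length(position))
  id[1] <- 1L
  for (i in seq_along(position)[-1]) {
    boundary <- index[i] >= index[i - 1] || position[i] <= position[i - 1]
    id[i] <- id[i - 1] + as.integer(boundary)
  }
  id
}

# brute-force Mk likelihood: sum over all internal-state assignments
oracle_mk_loglik <- function(tree, states, q, state_levels,
                             prior = NULL) {
  k <- nrow(q)
  n_tip <- length(tree$tip.label)
  prior <- prior %||% rep(1 / k, k)
  pm <- lapply(seq_len(nrow(tree$edge)),
               function(i) as.matrix(Matrix::expm(q * tree$edge.length[i])))
  internal <- n_tip + seq_len(tree$Nnode)
  grid <- expand.grid(rep(list(seq_len(k)), tree$Nnode))
  total <- 0
  tip_idx <- match(states[tree$tip.label], state_levels)
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(tip_idx, as.integer(grid[g, ]))
    pr <- prior[assign_[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * pm[[e]][assign_[tree$edge[e, 1]], assign_[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  log(total)
}

`%||%` <- rlang::`%||%`

extdata <- function(...) {
  system.file("extdata", ..., package = "zahnreihen", mustWork = TRUE)
}
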