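# Stochastic character mapping: joint sampling of ancestral node states
# conditional on tip states and a rate matrix, plus simulation of full
# branch histories conditional on their endpoint states (rejection
# sampling with a uniformization fallback).

#' Sample stochastic character maps
#'
#' Draws `n_maps` complete character histories conditional on the observed
#' tip states and generator `Q`. Node states are sampled from their joint
#' conditional distribution (pruning partials combined pre-order with the
#' branch transition probabilities); each branch history is then simulated
#' conditional on its endpoint states by rejection sampling (capped at
#' `max_rejects` attempts) with an exact uniformization sampler as
#' fallback.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to draw (>= 1).
#' @param seed Optional integer seed; the same seed and inputs reproduce
#'   the identical map collection.
#' @param max_rejects Rejection-sampling cap per branch before switching
#'   to uniformization.
#' @return An object of class `"stochastic_map_set"`: a list of maps, each
#'   with `node_states` (named by node number) and `histories` (per edge, a
#'   named numeric vector of dwell times whose names are states, in order
#'   along the branch), plus attributes `tree`, `q`, `state_levels`.
#' @export
simmap_sample <- function(tree, states, q, n_maps = 1, seed = NULL,
                          root_prior = "flat", state_levels = NULL,
                          max_rejects = 1000) {
  if (n_maps < 1) zr_abort("n_maps must be >= 1", "zr_error_validation")
  if (!is.null(seed)) set.seed(seed)
  pr <- mk_prune(tree, states, q, root_prior, state_levels)
  if (!is.finite(pr$loglik)) {
    zr_abort("tip states have zero probability under Q", "zr_error_domain")
  }
  k <- nrow(q)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  post <- ape::reorder.phylo(tree, "postorder")
  pmats <- pr$pmats
  pre_edges <- rev(seq_len(nrow(post$edge)))   # preorder over edges

  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(n_tip + tree$Nnode)
    w_root <- pr$prior * pr$partial[root, ]
    node_state[root] <- sample.int(k, 1, prob = w_root)
    histories <- vector("list", nrow(tree$edge))
    for (e in pre_edges) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      w <- pmats[[e]][node_state[p], ] * pr$partial[ch, ]
      if (sum(w) <= 0) {
        zr_abort("zero-probability endpoint pair on a branch",
                 "zr_error_domain")
      }
      node_state[ch] <- sample.int(k, 1, prob = w)
      histories[[e]] <- sample_branch_history(
        node_state[p], node_state[ch], post$edge.length[e], q,
        p_ab = pmats[[e]][node_state[p], node_state[ch]],
        max_rejects = max_rejects
      )
    }
    # re-key histories from postorder edge index to tree$edge row order
    edge_key <- match(paste(post$edge[, 1], post$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
    ordered <- vector("list", nrow(tree$edge))
    ordered[edge_key] <- histories
    maps[[m]] <- list(
      node_states = setNames(pr$state_levels[node_state],
                             seq_along(node_state)),
      histories = lapply(ordered, function(h) {
        setNames(h$times, pr$state_levels[h$states])
      })
    )
  }
  structure(maps, class = "stochastic_map_set", tree = tree, q = q,
            state_levels = pr$state_levels, seed = seed)
}

# Conditional CTMC path on one branch: states/times run from the parent
# end to the child end. Returns list(states = int vector, times = dwell
# times summing to t).
sample_branch_history <- function(a, b, t, q, p_ab, max_rejects = 1000) {
  k <- nrow(q)
  if (t <= 0 || all(abs(q) < 1e-300)) {
    if (a != b) {
      zr_abort("state change across a zero-length or rate-free branch",
               "zr_error_domain")
    }
    return(list(states = a, times = t))
  }
  # forward-simulation rejection is hopeless (and expensive) on branches
  # expecting many jumps; go straight to the exact conditional sampler
  if (max(-diag(q)) * t <= 20) {
    for (attempt in seq_len(max_rejects)) {
      path <- forward_path(a, t, q)
      if (path$states[length(path$states)] == b) return(path)
    }
  }
  uniformization_path(a, b, t, q, p_ab)
}

# unconditional forward simulation from state a over duration t
forward_path <- function(a, t, q) {
  states <- a
  times <- numeric(0)
  cur <- a
  elapsed <- 0
  repeat {
    rate <- -q[cur, cur]
    wait <- if (rate > 0) rexp(1, rate) else Inf
    if (elapsed + wait >= t) {
      times <- c(times, t - elapsed)
      return(list(states = states, times = times))
    }
    elapsed <- elapsed + wait
    times <- c(times, wait)
    probs <- q[cur, ]
    probs[cur] <- 0
    cur <- sample.int(nrow(q), 1, prob = probs)
    states <- c(states, cur)
  }
}

# exact endpoint-conditioned path via uniformization
uniformization_path <- function(a, b, t, q, p_ab, max_jumps = NULL) {
  k <- nrow(q)
  lam <- max(-diag(q))
  # jump counts beyond mean + 20 sd carry negligible mass
  max_jumps <- max_jumps %||%
    max(100, ceiling(lam * t + 20 * sqrt(lam * t) + 50))
  r <- diag(k) + q / lam
  # sample the number of uniformized jumps n | a, b, t
  u <- runif(1)
  cum <- 0
  rn <- diag(k)                 # R^0
  rpow <- list(rn)
  n <- -1L
  repeat {
    n <- n + 1L
    if (n > 0) {
      rn <- rn %*% r
      rpow[[n + 1L]] <- rn
    }
    pn <- dpois(n, lam * t) * rpow[[n + 1L]][a, b] / p_ab
    cum <- cum + pn
    if (u <= cum || n >= max_jumps) break
  }
  if (n == 0L) {
    if (a != b) zr_abort("uniformization sampled an impossible path",
                         "zr_error_internal")
    return(list(states = a, times = t))
  }
  # sample the uniformized chain s_0 = a, ..., s_n = b
  s <- integer(n + 1L)
  s[1] <- a
  s[n + 1L] <- b
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      w <- r[s[i], ] * rpow[[n - i + 1L]][, b]
      s[i + 1L] <- sample.int(k, 1, prob = w)
    }
  }
  jump_times <- sort(runif(n, 0, t))
  # collapse virtual jumps (self-transitions)
  states <- s[1]
  times <- numeric(0)
  last_time <- 0
  for (i in seq_len(n)) {
    if (s[i + 1L] != s[i]) {
      times <- c(times, jump_times[i] - last_time)
      last_time <- jump_times[i]
      states <- c(states, s[i + 1L])
    }
  }
  times <- c(times, t - last_time)
  list(states = states, times = times)
}

#' Dwell times of one stochastic map
#'
#' @param map One element of a [simmap_sample()] result.
#' @param state_levels State names (taken from the map's history names).
#' @return A tibble: `edge` (row of `tree$edge`), `state`, `time`.
#' @export
map_dwell_times <- function(map, state_levels = NULL) {
  purrr::imap_dfr(map$histories, function(h, e) {
    tibble(edge = e, state = names(h), time = as.numeric(h))
  })
}

#' Node-state posterior frequencies across maps
#'
#' @param maps A `stochastic_map_set` (or plain list of maps).
#' @return A tibble: `node`, `state`, `frequency` (share of maps with that
#'   node state).
#' @export
node_state_posterior <- function(maps) {
  purrr::imap_dfr(unclass(maps), function(m, i) {
    tibble(map = i, node = as.integer(names(m$node_states)),
           state = as.character(m$node_states))
  }) |>
    count(.data$node, .data$state) |>
    group_by(.data$node) |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("node", "state", "frequency")
}

#' Model-averaged stochastic maps and ancestral-state estimate
#'
#' Allocates `total` stochastic maps across fitted rate models in
#' proportion to their Akaike weights (rounded with a largest-remainder
#' correction so the total is exact), samples them under each model's ML
#' rate matrix, and summarises per-node state frequencies across all maps.
#' The root row of the summary is the ancestral-state estimate.
#'
#' @param fits An `mk_fit_set` (weighted fits from [fit_mk_models()] /
#'   [akaike_weights()]).
#' @param total Total number of maps (default 1000).
#' @param seed Optional integer seed.
#' @param max_rejects Passed to [simmap_sample()].
#' @return An object of class `"asr_result"`: list with `allocation`
#'   (tibble model/weight/n_maps), `maps` (combined list), `node_posterior`
#'   (tibble), `root_posterior` (tibble, root node only) and `fits`.
#' @export
model_averaged_maps <- function(fits, total = 1000, seed = NULL,
                                max_rejects = 1000) {
  if (inherits(fits, "mk_fit")) fits <- list(fits)
  w <- vapply(fits, function(f) f$akaike_weight %||% NA_real_, numeric(1))
  if (any(is.na(w))) {
    zr_abort("fits carry no Akaike weights; run akaike_weights() first",
             "zr_error_validation")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    zr_abort("Akaike weights must sum to 1", "zr_error_validation")
  }
  if (total < sum(w > 0)) {
    zr_abort(
      "total maps is smaller than the number of models with nonzero weight",
      "zr_error_allocation"
    )
  }
  n_m <- largest_remainder(total * w)
  if (!is.null(seed)) set.seed(seed)
  all_maps <- list()
  for (i in seq_along(fits)) {
    if (n_m[i] == 0) next
    f <- fits[[i]]
    ms <- simmap_sample(f$tree, f$states, f$q, n_maps = n_m[i],
                        root_prior = f$root_prior,
                        state_levels = f$state_levels,
                        max_rejects = max_rejects)
    all_maps <- c(all_maps, unclass(ms))
  }
  node_post <- node_state_posterior(all_maps)
  n_tip <- length(fits[[1]]$tree$tip.label)
  root_post <- filter(node_post, .data$node == n_tip + 1L)
  structure(list(
    allocation = tibble(
      model = vapply(fits, function(f) f$model, character(1)),
      akaike_weight = w,
      n_maps = n_m
    ),
    maps = all_maps,
    node_posterior = node_post,
    root_posterior = arrange(root_post, desc(.data$frequency)),
    fits = fits
  ), class = "asr_result")
}

# integer allocation of `shares` (summing to an integer total) by largest
# remainder
largest_remainder <- function(shares) {
  base <- floor(shares)
  remainder <- shares - base
  short <- round(sum(shares)) - sum(base)
  if (short > 0) {
    top_up <- order(remainder, decreasing = TRUE)[seq_len(short)]
    base[top_up] <- base[top_up] + 1
  }
  as.integer(base)
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Model-averaged stochastic character maps\n\nAllocation:\n")
  print(x$allocation)
  cat("\nRoot-state posterior (ancestral-state estimate):\n")
  print(x$root_posterior)
  invisible(x)
}

#' @describeIn model_averaged_maps Tidy per-node posterior frequencies.
#' @param x An `asr_result`.
#' @param ... Unused.
#' @export
tidy.asr_result <- function(x, ...) {
  x$node_posterior
}

#' @describeIn model_averaged_maps One-row summary: total maps, root mode
#'   and its posterior frequency.
#' @export
glance.asr_result <- function(x, ...) {
  tibble(
    n_maps = sum(x$allocation$n_maps),
    n_models = sum(x$allocation$n_maps > 0),
    root_state = x$root_posterior$state[1],
    root_frequency = x$root_posterior$frequency[1]
  )
}
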