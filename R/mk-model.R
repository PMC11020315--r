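# Mk (k-state continuous-time Markov) models for a discrete character on a
# phylogeny: pruning likelihood, ML fitting of ER/SYM/ARD rate structures,
# and Akaike-weight model comparison.

#' Build a rate matrix from a model structure and free rates
#'
#' @param model `"ER"` (one rate), `"SYM"` (one rate per unordered state
#'   pair) or `"ARD"` (one rate per ordered pair).
#' @param rates Numeric vector of free rates, in the order given by
#'   [mk_rate_index()].
#' @param k Number of states.
#' @return A k x k generator matrix (rows sum to zero).
#' @export
mk_build_q <- function(model, rates, k) {
  idx <- mk_rate_index(model, k)
  if (length(rates) != max(idx, na.rm = TRUE)) {
    zr_abort(paste0(model, " on ", k, " states needs ",
                    max(idx, na.rm = TRUE), " rate(s)"),
             "zr_error_validation")
  }
  if (any(rates < 0)) {
    zr_abort("rates must be non-negative", "zr_error_validation")
  }
  q <- matrix(0, k, k)
  off <- !diag(k)
  q[off] <- rates[idx[off]]
  diag(q) <- -rowSums(q)
  q
}

#' Free-rate index matrix of an Mk model structure
#'
#' Maps each off-diagonal transition (i, j) to the index of its free rate:
#' all ones for ER; upper-triangle order shared symmetrically for SYM; row
#' by row for ARD.
#'
#' @inheritParams mk_build_q
#' @return Integer k x k matrix (NA on the diagonal).
#' @export
mk_rate_index <- function(model, k) {
  model <- match.arg(model, c("ER", "SYM", "ARD"))
  idx <- matrix(NA_integer_, k, k)
  counter <- 0L
  if (model == "ER") {
    idx[!diag(k)] <- 1L
  } else if (model == "SYM") {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      counter <- counter + 1L
      idx[i, j] <- counter
      idx[j, i] <- counter
    }
  } else {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) {
        counter <- counter + 1L
        idx[i, j] <- counter
      }
    }
  }
  idx
}

check_generator <- function(q) {
  if (!is.matrix(q) || nrow(q) != ncol(q)) {
    zr_abort("Q must be a square matrix", "zr_error_domain")
  }
  off <- q[!diag(nrow(q))]
  if (any(off < -1e-12) || any(abs(rowSums(q)) > 1e-8)) {
    zr_abort("Q is not a valid generator (off-diagonals >= 0, rows sum to 0)",
             "zr_error_domain")
  }
  invisible(q)
}

# tip state tibble/vector -> named character vector
as_state_vector <- function(states) {
  if (is.data.frame(states)) {
    if (!all(c("taxon", "state") %in% names(states))) {
      zr_abort("`states` needs columns `taxon` and `state`",
               "zr_error_format")
    }
    return(setNames(as.character(states$state), states$taxon))
  }
  if (is.null(names(states))) {
    zr_abort("`states` must be named by taxon", "zr_error_format")
  }
  setNames(as.character(states), names(states))
}

# Per-branch transition probability matrices from one spectral
# decomposition of Q: P(t) = sum_j exp(lambda_j t) * v_j (w_j)^T, assembled
# for all branch lengths with a single matrix product. Falls back to
# ape::matexpo() when Q is numerically defective.
transition_probs <- function(q, times) {
  k <- nrow(q)
  eig <- tryCatch(eigen(q), error = function(e) NULL)
  if (!is.null(eig)) {
    vinv <- tryCatch(solve(eig$vectors), error = function(e) NULL)
    # accept the decomposition only if it reconstructs Q
    if (!is.null(vinv) &&
        max(abs(Re(eig$vectors %*% (eig$values * vinv)) - q)) <=
          1e-8 * max(1, max(abs(q)))) {
      # column j of `modes` is vec(v_j w_j^T), so vec(P(t)) = modes %*% e^{lambda t}
      modes <- vapply(seq_len(k),
                      function(j) as.vector(outer(eig$vectors[, j],
                                                  vinv[j, ])),
                      rep(eig$values[1] * 0, k * k))
      evt <- exp(outer(eig$values, times))          # k x n_times
      pvec <- Re(modes %*% evt)
      pvec[pvec < 0] <- 0
      return(lapply(seq_along(times), function(e) {
        p <- matrix(pvec[, e], k, k)
        p / rowSums(p)
      }))
    }
  }
  lapply(times, function(t) as.matrix(Matrix::expm(q * t)))
}

# root prior vector from a specification
root_prior_vector <- function(root_prior, q, k) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-8) {
      zr_abort("numeric root prior must be a length-k probability vector",
               "zr_error_domain")
    }
    return(root_prior)
  }
  root_prior <- match.arg(root_prior, c("flat", "stationary"))
  if (root_prior == "flat") return(rep(1 / k, k))
  stationary_dist(q)
}

stationary_dist <- function(q) {
  k <- nrow(q)
  a <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- tryCatch(as.vector(qr.solve(a, b)), error = function(e) rep(1 / k, k))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

# Pruning machinery, split into a one-time preparation step (tree
# reordering, tip-state matching) and a fast core, so ML fitting does not
# repeat the bookkeeping on every likelihood evaluation.
mk_prep <- function(tree, states, k, state_levels = NULL) {
  states <- as_state_vector(states)
  state_levels <- state_levels %||% sort(unique(stats::na.omit(states)))
  if (length(state_levels) > k) {
    zr_abort("more observed states than rows of Q", "zr_error_domain")
  }
  state_levels <- c(state_levels,
                    rep(NA_character_, k - length(state_levels)))
  if (is.null(tree$edge.length)) {
    zr_abort("tree has no branch lengths", "zr_error_domain")
  }
  if (any(tree$edge.length < 0)) {
    zr_abort("negative branch lengths", "zr_error_domain")
  }
  n_tip <- length(tree$tip.label)
  missing_taxa <- setdiff(tree$tip.label, names(states))
  if (length(missing_taxa) > 0) {
    zr_abort(paste0("no character state for taxon/taxa: ",
                    paste(missing_taxa, collapse = ", ")),
             "zr_error_validation")
  }
  post <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  tip_partial <- matrix(1, n_tip, k)
  for (i in seq_len(n_tip)) {
    s <- states[[tree$tip.label[i]]]
    if (!is.na(s)) {
      si <- match(s, state_levels)
      if (is.na(si)) {
        zr_abort(paste0("state `", s, "` not in state levels"),
                 "zr_error_validation")
      }
      tip_partial[i, ] <- 0
      tip_partial[i, si] <- 1
    }
  }
  list(edge = post$edge, edge.length = post$edge.length, n_tip = n_tip,
       n_node = n_node, tip_partial = tip_partial,
       state_levels = state_levels, k = k)
}

mk_prune_core <- function(prep, q, root_prior = "flat") {
  k <- prep$k
  pmats <- transition_probs(q, prep$edge.length)
  partial <- matrix(1, prep$n_node, k)
  partial[seq_len(prep$n_tip), ] <- prep$tip_partial
  log_scale <- 0
  done <- logical(prep$n_node)
  for (e in seq_len(nrow(prep$edge))) {
    p <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
    lik_ch <- pmats[[e]] %*% partial[ch, ]
    if (!done[p]) {
      partial[p, ] <- lik_ch
      done[p] <- TRUE
    } else {
      partial[p, ] <- partial[p, ] * lik_ch
    }
    m <- max(partial[p, ])
    if (m <= 0) {
      return(list(loglik = -Inf, partial = partial, log_scale = -Inf,
                  state_levels = prep$state_levels, pmats = pmats))
    }
    partial[p, ] <- partial[p, ] / m
    log_scale <- log_scale + log(m)
  }
  root <- prep$n_tip + 1L
  prior <- root_prior_vector(root_prior, q, k)
  loglik <- log(sum(prior * partial[root, ])) + log_scale
  list(loglik = loglik, partial = partial, log_scale = log_scale,
       state_levels = prep$state_levels, prior = prior, pmats = pmats)
}

mk_prune <- function(tree, states, q, root_prior = "flat",
                     state_levels = NULL) {
  check_generator(q)
  prep <- mk_prep(tree, states, nrow(q), state_levels)
  mk_prune_core(prep, q, root_prior)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of observed tip states under a k-state
#' continuous-time Markov model with generator `Q`, by post-order pruning
#' with per-branch transition probabilities `expm(Q t)` and a root prior.
#'
#' @param tree A `phylo` tree with branch lengths (e.g. from
#'   [calibrate_equal()]).
#' @param states Tip states: a tibble (`taxon`, `state`) or a named
#'   character vector. `NA` marks a missing observation.
#' @param q Generator matrix (rows sum to 0, off-diagonals >= 0).
#' @param root_prior `"flat"` (default), `"stationary"`, or a length-k
#'   probability vector.
#' @param state_levels Optional explicit state ordering matching the rows
#'   of `q`; defaults to the sorted observed states.
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q, root_prior = "flat",
                      state_levels = NULL) {
  mk_prune(tree, states, q, root_prior, state_levels)$loglik
}

#' Fit an Mk model by maximum likelihood
#'
#' Estimates the free transition rates of an ER, SYM or ARD model by
#' bounded multistart optimisation on log-rates. Likelihood surfaces on
#' small trees are flat, so several deterministic starting points spanning
#' two orders of magnitude around a heuristic rate scale are used.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_starts Number of optimisation starts (>= 1; default 5).
#' @param root_prior Root prior used in the likelihood.
#' @return An object of class `"mk_fit"`: list with `model`, `q` (ML
#'   generator), `rates`, `loglik`, `k_params`, `aic`, `state_levels`,
#'   `root_prior`, and the data (`tree`, `states`).
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM", "ARD"),
                   n_starts = 5, root_prior = "flat",
                   state_levels = NULL) {
  model <- match.arg(model)
  sv <- as_state_vector(states)
  observed <- unique(stats::na.omit(sv[tree$tip.label]))
  if (length(observed) < 2) {
    zr_abort("tip states are monomorphic; rates are not estimable",
             "zr_error_degenerate")
  }
  state_levels <- state_levels %||% sort(unique(stats::na.omit(sv)))
  k <- length(state_levels)
  n_par <- max(mk_rate_index(model, k), na.rm = TRUE)

  # heuristic scale: roughly one change per unit of total tree length
  base_rate <- max(1 / sum(tree$edge.length), 1e-8)
  start_grid <- base_rate * 10^seq(-1, 1.5, length.out = max(n_starts, 1))

  # Beyond ~100 expected changes on an average branch the likelihood is on
  # its saturation plateau and the rate is unidentifiable; bounding the
  # search there keeps estimates interpretable (and downstream history
  # simulation tractable).
  rate_max <- 100 / mean(tree$edge.length[tree$edge.length > 0])

  prep <- mk_prep(tree, sv, k, state_levels)
  nll <- function(logr) {
    rates <- exp(logr)
    if (any(!is.finite(rates)) || any(rates > rate_max)) return(1e10)
    q <- mk_build_q(model, rates, k)
    ll <- mk_prune_core(prep, q, root_prior)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (s in start_grid) {
    fit <- if (n_par == 1) {
      o <- optimize(function(lr) nll(lr), interval = log(s) + c(-8, 8),
                    tol = 1e-10)
      list(par = o$minimum, value = o$objective)
    } else {
      # cheap derivative-free exploration per start; the winner is
      # polished with a quasi-Newton pass below
      o <- optim(rep(log(s), n_par), nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 500))
      list(par = o$par, value = o$value)
    }
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (n_par > 1) {
    o <- nlminb(best$par, nll, control = list(rel.tol = 1e-10,
                                              iter.max = 1000))
    if (o$objective < best$value) best <- list(par = o$par,
                                               value = o$objective)
  }

  rates <- exp(best$par)
  q <- mk_build_q(model, rates, k)
  loglik <- -best$value
  structure(list(
    model = model,
    q = q,
    rates = rates,
    loglik = loglik,
    k_params = n_par,
    aic = 2 * n_par - 2 * loglik,
    state_levels = state_levels,
    root_prior = root_prior,
    tree = tree,
    states = sv
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, "), ", length(x$state_levels),
      " states\n", sep = "")
  cat("  logLik:", format(x$loglik), "  AIC:", format(x$aic),
      "  free rates:", x$k_params, "\n")
  if (!is.null(x$akaike_weight)) {
    cat("  Akaike weight:", format(x$akaike_weight), "\n")
  }
  invisible(x)
}

#' @describeIn fit_mk Tidy the estimated rate matrix: one row per ordered
#'   state pair with its rate.
#' @param x An `mk_fit` object.
#' @param ... Unused.
#' @export
tidy.mk_fit <- function(x, ...) {
  k <- length(x$state_levels)
  idx <- mk_rate_index(x$model, k)
  out <- tidyr::expand_grid(from = x$state_levels, to = x$state_levels) |>
    filter(.data$from != .data$to)
  out$rate <- unname(mapply(function(f, t) {
    x$q[match(f, x$state_levels), match(t, x$state_levels)]
  }, out$from, out$to))
  out$term <- paste0(out$from, "->", out$to)
  select(out, "term", "from", "to", "rate")
}

#' @describeIn fit_mk One-row model summary (logLik, AIC, weight).
#' @export
glance.mk_fit <- function(x, ...) {
  tibble(
    model = x$model,
    k_states = length(x$state_levels),
    k_params = x$k_params,
    loglik = x$loglik,
    aic = x$aic,
    akaike_weight = x$akaike_weight %||% NA_real_
  )
}

#' Fit the three candidate rate models
#'
#' Convenience wrapper fitting ER, SYM and ARD and attaching Akaike
#' weights.
#'
#' @inheritParams fit_mk
#' @param models Models to fit.
#' @return A list of class `"mk_fit_set"` of weighted `mk_fit` objects.
#' @export
fit_mk_models <- function(tree, states, models = c("ER", "SYM", "ARD"),
                          n_starts = 5, root_prior = "flat",
                          state_levels = NULL) {
  fits <- lapply(models, function(m) {
    fit_mk(tree, states, model = m, n_starts = n_starts,
           root_prior = root_prior, state_levels = state_levels)
  })
  names(fits) <- models
  fits <- akaike_weights(fits)
  structure(fits, class = "mk_fit_set")
}

#' Akaike weights across fitted models
#'
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with
#' `delta_m = AIC_m - min(AIC)`.
#'
#' @param fits A list of `mk_fit` objects (or an `mk_fit_set`).
#' @return The same list with an `akaike_weight` element set on each fit;
#'   weights sum to 1.
#' @export
akaike_weights <- function(fits) {
  if (inherits(fits, "mk_fit")) fits <- list(fits)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]$akaike_weight <- w[i]
  fits
}

#' @export
print.mk_fit_set <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @describeIn fit_mk_models Model-comparison table across the set.
#' @param x An `mk_fit_set`.
#' @param ... Unused.
#' @export
glance.mk_fit_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}
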