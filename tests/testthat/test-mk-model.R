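test_that("rate matrices have the right structure and parameter counts", {
  expect_equal(max(mk_rate_index("ER", 3), na.rm = TRUE), 1)
  expect_equal(max(mk_rate_index("SYM", 3), na.rm = TRUE), 3)
  expect_equal(max(mk_rate_index("ARD", 3), na.rm = TRUE), 6)
  q <- mk_build_q("SYM", c(0.1, 0.2, 0.3), 3)
  expect_equal(rowSums(q), rep(0, 3))
  expect_equal(q, t(q))
  expect_error(mk_build_q("ER", c(1, 2), 3), class = "zr_error_validation")
})

test_that("a rate-free cherry returns pure root-prior mass", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  q <- matrix(0, 3, 3)
  ll <- mk_loglik(tr, c(A = "s1", B = "s1"), q,
                  state_levels = c("s1", "s2", "s3"))
  expect_equal(ll, log(1 / 3))
})

test_that("single-branch two-state probabilities match the closed form", {
  # P(no observed change) = (1 + exp(-2qt)) / 2 from a known root state
  qr <- 0.3
  t <- 1.7
  q <- mk_build_q("ER", qr, 2)
  # cherry with one zero branch pins the root state
  tr <- ape::read.tree(text = paste0("(A:0,B:", t, ");"))
  ll_same <- mk_loglik(tr, c(A = "x", B = "x"), q,
                       root_prior = c(1, 0), state_levels = c("x", "y"))
  expect_equal(exp(ll_same), (1 + exp(-2 * qr * t)) / 2, tolerance = 1e-10)
  ll_diff <- mk_loglik(tr, c(A = "x", B = "y"), q,
                       root_prior = c(1, 0), state_levels = c("x", "y"))
  expect_equal(exp(ll_diff), (1 - exp(-2 * qr * t)) / 2, tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on all small trees", {
  topologies <- c(
    "(A:1,B:2);",
    "((A:1,B:1):0.5,C:2);",
    "((A:0.4,B:1.1):0.6,(C:0.8,D:0.2):1.2);",
    "(((A:1,B:1):1,C:2):0.5,(D:1,E:2):1);"
  )
  set.seed(7)
  lev <- c("s1", "s2", "s3")
  for (nwk in topologies) {
    tr <- ape::read.tree(text = nwk)
    n <- length(tr$tip.label)
    for (model in c("ER", "ARD")) {
      npar <- max(mk_rate_index(model, 3), na.rm = TRUE)
      q <- mk_build_q(model, runif(npar, 0.05, 0.6), 3)
      states <- setNames(sample(lev, n, replace = TRUE), tr$tip.label)
      expect_equal(mk_loglik(tr, states, q, state_levels = lev),
                   oracle_mk_loglik(tr, states, q, lev),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to re-rooting for reversible Q with stationary prior", {
  set.seed(13)
  tr <- ape::rtree(6)
  lev <- c("s1", "s2", "s3")
  q <- mk_build_q("SYM", runif(3, 0.1, 0.5), 3)   # symmetric => reversible
  states <- setNames(sample(lev, 6, replace = TRUE), tr$tip.label)
  ll0 <- mk_loglik(tr, states, q, root_prior = "stationary",
                   state_levels = lev)
  for (node in c(8, 9)) {
    rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
    expect_equal(mk_loglik(rerooted, states, q, root_prior = "stationary",
                           state_levels = lev),
                 ll0, tolerance = 1e-8)
  }
})

test_that("fitted models respect nesting and report parameter counts", {
  set.seed(21)
  tr <- ape::rtree(25)
  tr$edge.length <- tr$edge.length * 5
  lev <- c("s1", "s2", "s3")
  tips <- simulate_mk_tips(tr, mk_build_q("ER", 0.08, 3),
                           state_levels = lev, root_state = "s1", seed = 2)
  fits <- fit_mk_models(tr, tips, state_levels = lev)
  g <- glance(fits)
  expect_equal(g$k_params, c(1, 3, 6))
  # nested models: fuller models fit at least as well (optimizer tolerance)
  expect_gte(g$loglik[g$model == "SYM"], g$loglik[g$model == "ER"] - 1e-6)
  expect_gte(g$loglik[g$model == "ARD"], g$loglik[g$model == "SYM"] - 1e-6)
  # estimated generators are valid
  for (f in fits) {
    expect_equal(rowSums(f$q), rep(0, 3), tolerance = 1e-12)
    expect_true(all(f$q[!diag(3)] >= 0))
  }
  expect_error(fit_mk(tr, setNames(rep("s1", 25), tr$tip.label), "ER"),
               class = "zr_error_degenerate")
})

test_that("ML estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(31)
  tr <- ape::rtree(30)
  tr$edge.length <- tr$edge.length * 8
  lev <- c("s1", "s2")
  tips <- simulate_mk_tips(tr, mk_build_q("ER", 0.05, 2),
                           state_levels = lev, root_state = "s1", seed = 4)
  ours <- fit_mk(tr, tips, "ER", state_levels = lev)
  x <- setNames(tips$state, tips$taxon)
  theirs <- phytools::fitMk(tr, x, model = "ER", pi = rep(0.5, 2))
  expect_equal(ours$loglik, as.numeric(stats::logLik(theirs)),
               tolerance = 1e-4)
  expect_equal(ours$rates[1], theirs$rates[1], tolerance = 0.01)
})

test_that("Akaike weights follow the exp(-delta/2) formula", {
  f <- function(aic) structure(list(aic = aic, model = "ER"),
                               class = "mk_fit")
  w3 <- sapply(akaike_weights(list(f(10), f(10), f(10))),
               function(x) x$akaike_weight)
  expect_equal(w3, rep(1 / 3, 3))
  w2 <- sapply(akaike_weights(list(f(10), f(12))),
               function(x) x$akaike_weight)
  expect_equal(round(w2, 3), c(0.731, 0.269))
  expect_equal(sum(w2), 1, tolerance = 1e-9)
  w1 <- akaike_weights(list(f(5)))[[1]]$akaike_weight
  expect_equal(w1, 1)
})

test_that("tidy and glance expose rates and model summaries", {
  set.seed(41)
  tr <- ape::rtree(12)
  lev <- c("s1", "s2")
  tips <- simulate_mk_tips(tr, mk_build_q("ER", 0.5, 2),
                           state_levels = lev, root_state = "s1", seed = 8)
  fit <- fit_mk(tr, tips, "ER", state_levels = lev)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)                     # two ordered pairs
  expect_equal(td$rate[1], td$rate[2])          # ER: shared rate
  expect_named(glance(fit),
               c("model", "k_states", "k_params", "loglik", "aic",
                 "akaike_weight"))
})
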