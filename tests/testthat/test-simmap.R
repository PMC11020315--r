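test_that("a rate-free character maps constantly", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  q <- matrix(0, 2, 2)
  maps <- simmap_sample(tr, c(A = "x", B = "x"), q, n_maps = 5, seed = 1,
                        state_levels = c("x", "y"))
  for (m in maps) {
    expect_true(all(m$node_states == "x"))
    for (h in m$histories) expect_equal(names(h), "x")
  }
})

test_that("node sampling matches the analytic conditional distribution", {
  # zero branch to tip A pins the root at state x; the internal node above
  # the (B, C) cherry then has a closed-form conditional distribution
  qr <- 0.4
  q <- mk_build_q("ER", qr, 2)
  lev <- c("x", "y")
  tr <- ape::read.tree(text = "(A:0,(B:1,C:1):1);")
  states <- c(A = "x", B = "x", C = "x")
  # analytic conditional for node n2 (parent of B, C), root pinned at x:
  p <- as.matrix(Matrix::expm(q * 1))
  w <- c(p[1, 1] * p[1, 1]^2, p[1, 2] * p[2, 1]^2)
  p_x <- w[1] / sum(w)
  n <- 10000
  maps <- simmap_sample(tr, states, q, n_maps = n, seed = 99,
                        root_prior = c(1, 0), state_levels = lev)
  freq_x <- mean(vapply(maps, function(m) m$node_states[["5"]] == "x",
                        logical(1)))
  mc_se <- sqrt(p_x * (1 - p_x) / n)
  expect_lt(abs(freq_x - p_x), 3 * mc_se + 1e-12)
})

test_that("maps honour tip states and conserve branch lengths", {
  set.seed(5)
  tr <- ape::rtree(8)
  lev <- c("s1", "s2", "s3")
  q <- mk_build_q("ARD", runif(6, 0.1, 0.8), 3)
  tips <- simulate_mk_tips(tr, q, state_levels = lev, root_state = "s1",
                           seed = 6)
  maps <- simmap_sample(tr, tips, q, n_maps = 25, seed = 7,
                        state_levels = lev)
  obs <- setNames(tips$state, tips$taxon)
  for (m in maps) {
    # tip states always equal observations
    for (i in seq_along(tr$tip.label)) {
      expect_equal(m$node_states[[as.character(i)]],
                   obs[[tr$tip.label[i]]])
    }
    # per-branch dwell times sum to the branch length
    for (e in seq_len(nrow(tr$edge))) {
      expect_equal(sum(m$histories[[e]]), tr$edge.length[e],
                   tolerance = 1e-9)
    }
    # history endpoints agree with the sampled node states
    for (e in seq_len(nrow(tr$edge))) {
      h <- m$histories[[e]]
      expect_equal(names(h)[1],
                   m$node_states[[as.character(tr$edge[e, 1])]])
      expect_equal(names(h)[length(h)],
                   m$node_states[[as.character(tr$edge[e, 2])]])
    }
  }
})

test_that("the same seed reproduces the identical map collection", {
  set.seed(15)
  tr <- ape::rtree(6)
  lev <- c("a", "b")
  q <- mk_build_q("ER", 0.4, 2)
  tips <- simulate_mk_tips(tr, q, state_levels = lev, root_state = "a",
                           seed = 16)
  m1 <- simmap_sample(tr, tips, q, n_maps = 10, seed = 77,
                      state_levels = lev)
  m2 <- simmap_sample(tr, tips, q, n_maps = 10, seed = 77,
                      state_levels = lev)
  expect_identical(unclass(m1)[], unclass(m2)[])
})

test_that("the uniformization fallback is exact on forced transitions", {
  # call the conditional sampler directly on a branch with differing
  # endpoints: every path must change state an odd number of times and
  # dwell times must fill the branch exactly
  q <- mk_build_q("ER", 3, 2)
  up <- getFromNamespace("uniformization_path", "zahnreihen")
  p <- as.matrix(Matrix::expm(q * 1))
  set.seed(8)
  n_changes <- replicate(2000, {
    path <- up(1, 2, 1, q, p[1, 2])
    length(path$states) - 1
  })
  expect_true(all(n_changes %% 2 == 1))     # odd change counts only
  expect_equal(sum(replicate(50, sum(up(1, 2, 1, q, p[1, 2])$times))),
               50, tolerance = 1e-9)
})

test_that("impossible endpoint pairs are an error", {
  q <- matrix(0, 2, 2)
  sbh <- getFromNamespace("sample_branch_history", "zahnreihen")
  expect_error(sbh(1, 2, 1, q, 0), class = "zr_error_domain")
})

test_that("map allocation follows Akaike weights with exact totals", {
  lr <- getFromNamespace("largest_remainder", "zahnreihen")
  expect_equal(lr(c(500, 300, 200)), c(500L, 300L, 200L))
  alloc <- lr(1000 * rep(1 / 3, 3))
  expect_equal(sum(alloc), 1000L)
  expect_true(all(abs(alloc - 1000 / 3) <= 1))
})

test_that("model-averaged maps allocate, combine and summarise", {
  set.seed(25)
  tr <- ape::rtree(10)
  tr$edge.length <- tr$edge.length * 4
  lev <- c("s1", "s2")
  tips <- simulate_mk_tips(tr, mk_build_q("ER", 0.1, 2),
                           state_levels = lev, root_state = "s1", seed = 26)
  fits <- fit_mk_models(tr, tips, models = c("ER", "ARD"),
                        state_levels = lev)
  asr <- model_averaged_maps(fits, total = 60, seed = 27)
  expect_equal(sum(asr$allocation$n_maps), 60)
  expect_equal(length(asr$maps), 60)
  expect_equal(asr$allocation$akaike_weight,
               vapply(fits, function(f) f$akaike_weight, numeric(1)),
               ignore_attr = TRUE)
  # posterior frequencies are proper
  post <- asr$node_posterior |>
    dplyr::group_by(node) |>
    dplyr::summarise(s = sum(frequency))
  expect_equal(post$s, rep(1, nrow(post)))
  expect_error(model_averaged_maps(fits, total = 1),
               class = "zr_error_allocation")
})
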