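test_that("noise-free dentitions recover their period by construction", {
  d <- simulate_dentition(n_positions = 12, period = 3, phase = 0,
                          noise_cv = 0)
  expect_equal(z_spacing(d)$mean_z, 3, tolerance = 1e-12)
  expect_equal(provenance(d)$period, 3)
  # every position carries one functional and one replacement tooth
  expect_equal(nrow(d), 24)
  # recorded true indices match what replacement_index() recomputes
  idx <- replacement_index(d)
  ri <- idx$replacement_index[idx$tooth_class == "replacement"]
  expect_equal(ri, provenance(d)$true_indices, tolerance = 1e-12)
})

test_that("noisy dentitions stay close to the true period", {
  d <- simulate_dentition(n_positions = 16, period = 2.5, noise_cv = 0.03,
                          seed = 42)
  expect_lt(abs(suppressWarnings(z_spacing(d))$mean_z - 2.5), 0.1)
  # a maxilla-like row with the published average as the true period
  d2 <- simulate_dentition(n_positions = 15, period = 2.53,
                           noise_cv = 0.03, seed = 43)
  expect_lt(abs(suppressWarnings(z_spacing(d2))$mean_z - 2.53), 0.1)
})

test_that("generators are deterministic under a fixed seed", {
  d1 <- simulate_dentition(period = 2.2, noise_cv = 0.05, seed = 9)
  d2 <- simulate_dentition(period = 2.2, noise_cv = 0.05, seed = 9)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  s1 <- simulate_increments(30, 12, cv = 0.2, seed = 10)
  s2 <- simulate_increments(30, 12, cv = 0.2, seed = 10)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  tr <- ape::rtree(10)
  q <- mk_build_q("ER", 0.3, 2)
  t1 <- simulate_mk_tips(tr, q, seed = 11)
  t2 <- simulate_mk_tips(tr, q, seed = 11)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("increment simulation honours its spec", {
  s <- simulate_increments(46, mean_width = 11.7, cv = 0.1, seed = 1)
  expect_equal(formation_time(s$width_um), 46)
  s0 <- simulate_increments(10, mean_width = 8, cv = 0)
  expect_equal(s0$width_um, rep(8, 10))
  expect_error(simulate_increments(0, 10), class = "zr_error_validation")
  expect_error(simulate_increments(10, -1), class = "zr_error_validation")
})

test_that("simulated characters follow the two-state closed form", {
  # tip differs from root with probability (1 - exp(-2qt)) / 2
  qr <- 0.3
  t <- 1.4
  tr <- ape::read.tree(text = paste0("(A:", t, ",B:0);"))
  q <- mk_build_q("ER", qr, 2)
  set.seed(55)
  flips <- replicate(10000, {
    tips <- simulate_mk_tips(tr, q, state_levels = c("x", "y"),
                             root_state = "x")
    tips$state[tips$taxon == "A"] != "x"
  })
  p_flip <- (1 - exp(-2 * qr * t)) / 2
  se <- sqrt(p_flip * (1 - p_flip) / 10000)
  expect_lt(abs(mean(flips) - p_flip), 3 * se + 1e-12)
  # rate-free evolution copies the root everywhere
  t0 <- simulate_mk_tips(ape::rtree(6), matrix(0, 2, 2),
                         state_levels = c("x", "y"), root_state = "y",
                         seed = 56)
  expect_true(all(t0$state == "y"))
  expect_true(all(attr(t0, "node_states") == "y"))
})

test_that("generator output round-trips through the file readers", {
  d <- simulate_dentition(period = 2.8, noise_cv = 0.02, seed = 12)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tooth_table(d, p)
  expect_equal(as.data.frame(read_tooth_table(p)), as.data.frame(d),
               tolerance = 1e-12, ignore_attr = TRUE)
  s <- simulate_increments(20, 10, cv = 0.1, seed = 13)
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s, p2)
  expect_equal(as.data.frame(read_increment_table(p2)), as.data.frame(s),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulate_dentition(n_positions = 3), "n_positions",
               class = "zr_error_validation")
  expect_error(simulate_dentition(period = 1), "period",
               class = "zr_error_validation")
  expect_error(simulate_dentition(noise_cv = 0.6), "noise_cv",
               class = "zr_error_validation")
})
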