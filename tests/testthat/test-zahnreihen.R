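test_that("segmentation splits maximal degressive runs", {
  s <- tibble::tibble(position = 1:6,
                      replacement_index = c(1.8, 1.4, 1.0, 1.9, 1.5, 1.1))
  ids <- segment_zahnreihen(s)$zahnreihe_id
  expect_equal(ids, c(1, 1, 1, 2, 2, 2))

  # single point
  expect_equal(segment_zahnreihen(s[1, ])$zahnreihe_id, 1L)

  # equal consecutive indices start a new Zahnreihe
  tie <- tibble::tibble(position = 1:3, replacement_index = c(1.5, 1.5, 1.0))
  expect_equal(segment_zahnreihen(tie)$zahnreihe_id, c(1, 2, 2))

  # two generations in one alveolus never share a wave
  pair <- tibble::tibble(position = c(1, 1), replacement_index = c(1.4, 0.4))
  expect_equal(segment_zahnreihen(pair)$zahnreihe_id, c(1, 2))
})

test_that("segmentation matches a brute-force run decomposition and partitions the series", {
  for (seed in 1:10) {
    d <- suppressWarnings(simulate_dentition(
      n_positions = 16, period = 3, noise_cv = if (seed > 5) 0.05 else 0,
      seed = seed))
    series <- family_series(suppressWarnings(replacement_index(d)))
    seg <- segment_zahnreihen(series)
    expect_equal(seg$zahnreihe_id,
                 oracle_runs(series$position, series$replacement_index))
    # strictly decreasing within every Zahnreihe; concatenation reproduces
    # the series
    for (z in split(seg, seg$zahnreihe_id)) {
      expect_true(all(diff(z$replacement_index) < 0) || nrow(z) == 1)
      expect_true(all(diff(z$position) > 0) || nrow(z) == 1)
    }
    expect_equal(dplyr::select(seg, -zahnreihe_id), series,
                 ignore_attr = TRUE)
  }
})

test_that("Z-spacing interpolates horizontally between successive polylines", {
  # two parallel straight Zahnreihen offset by exactly 3 positions
  a <- tibble::tibble(position = c(1, 2), replacement_index = c(1.8, 1.2),
                      zahnreihe_id = 1L)
  b <- tibble::tibble(position = c(4, 5), replacement_index = c(1.8, 1.2),
                      zahnreihe_id = 2L)
  res <- measure_z_spacing(dplyr::bind_rows(a, b))
  expect_equal(res$measurements[[1]], c(3, 3))
  expect_equal(res$mean_z, 3)
  expect_equal(res$n_zahnreihen, 2)

  # member outside the next polyline's index range is skipped
  c_ <- tibble::tibble(position = c(4, 5), replacement_index = c(1.5, 1.2),
                       zahnreihe_id = 2L)
  res2 <- measure_z_spacing(dplyr::bind_rows(a, c_))
  expect_equal(res2$n_measurements, 1)   # only the 1.2-level tooth matches

  # fewer than 2 Zahnreihen is an error
  expect_error(measure_z_spacing(a), class = "zr_error_undefined_spacing")
})

test_that("direction classification matches the 2.0 rule", {
  expect_equal(classify_direction(2.53), "rostral_to_caudal")
  expect_equal(classify_direction(2.0), "alternating")
  expect_equal(classify_direction(1.40), "caudal_to_rostral")
  # tolerance widens the alternating band
  expect_equal(classify_direction(2.05, tol = 0.1), "alternating")
  expect_error(classify_direction(-1), class = "zr_error_domain")
  expect_error(classify_direction(0), class = "zr_error_domain")
})

test_that("noise-free synthetic dentitions return their exact period", {
  for (p in c(1.5, 2.0, 2.5, 3.0, 3.5)) {
    d <- simulate_dentition(n_positions = 16, period = p, noise_cv = 0)
    expect_equal(z_spacing(d)$mean_z, p, tolerance = 1e-9)
  }
})

test_that("rows with a single Zahnreihe yield an empty cell, not an error", {
  # one degressive run: replacement maturity declines caudally across the
  # whole row, so no second wave exists to measure against
  one_wave <- as_tooth_table(tibble::tibble(
    specimen_id = "S1", element = "maxilla", side = "left",
    position = c(1L, 1L, 2L, 2L, 3L, 3L),
    tooth_class = rep(c("functional", "replacement"), 3),
    generation = rep(c(0L, 1L), 3),
    total_length_mm = c(10, 9, 10, 5, 10, 1)
  ))
  res <- z_spacing(one_wave)
  expect_true(is.na(res$mean_z))
  expect_equal(res$n_zahnreihen, 1)
})

test_that("summarize_jaw reproduces the published-table layout", {
  ztab <- readr::read_csv(extdata("jeholosaurus_zspacing.csv"),
                          show_col_types = FALSE)
  js <- summarize_jaw(ztab)
  expect_equal(nrow(js$by_specimen), 6)        # one row per specimen
  expect_equal(ncol(js$by_specimen), 7)        # id + six element/side cells
  expect_equal(js$by_specimen$maxilla_left[
    js$by_specimen$specimen_id == "IVPP V15717"], 2.82)
  # single specimen degenerates to that specimen's row
  one <- summarize_jaw(dplyr::filter(ztab, specimen_id == "CUGW VH132"))
  expect_equal(nrow(one$by_specimen), 1)
  expect_equal(tidy(one)$z_spacing, dplyr::filter(
    ztab, specimen_id == "CUGW VH132")$z_spacing)
})

test_that("summarize_jaw computes from raw teeth too", {
  d1 <- simulate_dentition(n_positions = 16, period = 2.5, noise_cv = 0,
                           specimen_id = "A", side = "left")
  d2 <- simulate_dentition(n_positions = 16, period = 3.0, noise_cv = 0,
                           specimen_id = "A", side = "right")
  js <- summarize_jaw(as_tooth_table(dplyr::bind_rows(d1, d2)))
  expect_equal(js$by_specimen$maxilla_left, 2.5)
  expect_equal(js$by_specimen$maxilla_right, 3.0)
  expect_equal(js$element_means$grand_mean, 2.75)
})
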