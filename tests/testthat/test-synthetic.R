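test_that("generated surfaces hit the target Ra and are seed-deterministic", {
  for (case in list(c(Ra = 86, seed = 1), c(Ra = 30, seed = 2),
                    c(Ra = 5, seed = 3), c(Ra = 200, seed = 4))) {
    sp <- surface_spec(48, 48, pixel_size = 50, target_Ra = case[["Ra"]],
                       seed = case[["seed"]])
    hm <- generate_height_map(sp)
    ra <- mean(vapply(extract_profiles(hm), compute_Ra, numeric(1)))
    expect_lt(abs(ra - case[["Ra"]]) / case[["Ra"]], 0.01)
  }
  sp <- surface_spec(32, 32, 50, 86, seed = 11)
  expect_identical(unclass(generate_height_map(sp)),
                   unclass(generate_height_map(sp)))
})

test_that("a lacuna carves a depression of the prescribed depth", {
  ps <- 35
  # centre exactly on a pixel centre so the quartic bump attains its depth
  ctr <- c((32 - 0.5) * ps, (32 - 0.5) * ps)
  sp <- surface_spec(64, 64, ps, target_Ra = 0.5, seed = 5,
                     lacunae = list(lacuna_spec(ctr, c(400, 300), depth = 500)))
  hm <- generate_height_map(sp)
  expect_lt(abs((min(hm) - stats::median(hm)) - (-500)), 5)
})

test_that("a lacuna reaching outside the scan area is rejected", {
  bad <- lacuna_spec(c(100, 100), c(400, 300), depth = 500)
  sp <- surface_spec(64, 64, 35, 10, lacunae = list(bad))
  expect_error(generate_height_map(sp), "outside")
})

test_that("the tilt plane is added last and leveling removes it exactly", {
  flat <- generate_height_map(surface_spec(32, 32, 50, 40, seed = 9))
  tilted <- generate_height_map(surface_spec(32, 32, 50, 40, seed = 9,
                                             tilt = c(2, 3)))
  expect_equal(unclass(level_height_map(tilted)),
               unclass(level_height_map(flat)), tolerance = 1e-10)
})

test_that("forward Hertz curves match an independent SI evaluation", {
  # constant E chosen so Zdefl(h = 100 nm) is ~10 nm
  cs <- curve_spec(E_profile = 0.0822, h_max = 100, n_contact = 100L,
                   noise_sd = 0)
  fc <- generate_force_curve(cs)
  i <- length(fc$Zpos)            # deepest sample, h = 100 nm
  h <- fc$Zpos[i] - fc$Zdefl[i]
  expect_equal(h, 100, tolerance = 1e-12)
  expect_equal(fc$Zdefl[i], 10, tolerance = 1e-3)
  expect_equal(fc$Zdefl[i], hertz_zdefl_si(0.0822, 100), tolerance = 1e-12)
})

test_that("force-curve generation validates the modulus and records contact", {
  expect_error(generate_force_curve(curve_spec(function(h) 1 - h / 50,
                                               h_max = 100)),
               "positive")
  fc <- generate_force_curve(curve_spec(1, n_baseline = 20L))
  expect_identical(fc$true_contact, 21L)
  expect_identical(fc$Zpos[fc$true_contact], 0)
  expect_true(all(fc$Zdefl[seq_len(fc$true_contact)] == 0))
  # seeded noise is reproducible
  f1 <- generate_force_curve(curve_spec(1, noise_sd = 0.1, seed = 7))
  f2 <- generate_force_curve(curve_spec(1, noise_sd = 0.1, seed = 7))
  expect_identical(f1$Zdefl, f2$Zdefl)
})

test_that("dehydration series follow the power law and the seed", {
  s0 <- generate_dehydration_series(3.5, -0.2, times = 0, noise_sd = 0)
  expect_equal(s0$m, 3.5)
  s <- generate_dehydration_series(1, -14 / 99, times = c(0, 6, 12),
                                   noise_sd = 0)
  expect_equal(s$m[3], exp(-14 / 99 * log(13)), tolerance = 1e-12)
  expect_equal(round(s$m[3], 4), 0.6958)
  a <- generate_dehydration_series(1, -0.14, 0:10, noise_sd = 0.02, seed = 3)
  b <- generate_dehydration_series(1, -0.14, 0:10, noise_sd = 0.02, seed = 3)
  expect_identical(a$m, b$m)
  expect_error(generate_dehydration_series(1, -0.14, times = c(-1, 2)), "times")
  expect_error(generate_dehydration_series(1, 0.1, times = 0:3), "drying")
})
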