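test_that("the Hertz point formula agrees with an all-SI evaluation", {
  expect_equal(compute_E_point(10, 100), 0.0822, tolerance = 1e-3)
  expect_equal(compute_E_point(10, 100), hertz_E_si(10, 100),
               tolerance = 1e-12)
  # parameter sweep against the independent oracle
  set.seed(2)
  for (i in 1:20) {
    V <- runif(1, 0, 0.5); k <- runif(1, 0.01, 0.36); R <- runif(1, 10, 60)
    zd <- runif(1, 1, 50); h <- runif(1, 10, 500)
    expect_equal(compute_E_point(zd, h, hertz_params(V, k, R)),
                 hertz_E_si(zd, h, V, k, R), tolerance = 1e-9)
  }
})

test_that("E scales linearly in Zdefl and k, and as 1/sqrt(R)", {
  p <- hertz_params()
  expect_equal(compute_E_point(0, 50, p), 0)
  expect_equal(compute_E_point(20, 50, p), 2 * compute_E_point(10, 50, p))
  p2 <- hertz_params(k = 2 * p$k)
  expect_equal(compute_E_point(10, 50, p2), 2 * compute_E_point(10, 50, p))
  p4 <- hertz_params(R = 4 * p$R)
  expect_equal(compute_E_point(10, 50, p4), compute_E_point(10, 50, p) / 2)
  expect_error(compute_E_point(10, 5), "h_min")
  expect_error(compute_E_point(-1, 50), ">= 0")
})

test_that("indentation depth is the stage travel minus the deflection", {
  mk <- function(zd) force_curve(Zpos = c(-40, -30, -20, -10, 0, 30, 70, 110),
                                 Zdefl = zd)
  # soft contact: Zpos 110, Zdefl 10 -> h = 100
  d <- compute_indentation_depth(mk(c(0, 0, 0, 0, 0, 2, 5, 10)), contact = 5)
  expect_equal(d$h, c(0, 28, 65, 100))
  # rigid surface: Zdefl tracks Zpos -> h = 0
  rigid <- mk(c(0, 0, 0, 0, 0, 30, 70, 110))
  expect_equal(compute_indentation_depth(rigid, 5)$h, rep(0, 4))
  # free cantilever: Zdefl = 0 -> h = Zpos
  free <- mk(rep(0, 8))
  expect_equal(compute_indentation_depth(free, 5)$h, c(0, 30, 70, 110))
  # inconsistent contact point errors
  bad <- mk(c(0, 0, 0, 0, 0, 40, 80, 120))
  expect_error(compute_indentation_depth(bad, 5), "negative indentation")
})

test_that("contact detection finds the first departure from the baseline", {
  fc <- generate_force_curve(curve_spec(1, n_baseline = 30L, noise_sd = 0))
  det <- detect_contact_point(fc)
  expect_identical(det$index, which(fc$Zdefl > 0)[1])
  expect_identical(det$touch, fc$true_contact)  # last at-baseline sample
  expect_equal(det$baseline, 0)
  flatc <- force_curve(Zpos = seq(-100, 40, by = 10), Zdefl = rep(0, 15))
  expect_error(detect_contact_point(flatc), "no contact")
})

test_that("noiseless round trips recover the prescribed modulus", {
  # constant E
  pr <- compute_E_profile(generate_force_curve(curve_spec(1.0, noise_sd = 0)))
  expect_true(all(abs(pr$E - 1.0) < 0.001))
  # declining E: recovered within 0.5% at every depth, and monotone
  Ef <- function(h) 1.7 + (0.5 - 1.7) * h / 200
  pr2 <- compute_E_profile(generate_force_curve(curve_spec(Ef, noise_sd = 0)))
  expect_true(all(abs(pr2$E - Ef(pr2$h)) / Ef(pr2$h) < 0.005))
  expect_true(all(diff(pr2$E) < 0))
  # degenerate: nothing at or beyond h_min
  shallow <- generate_force_curve(curve_spec(1, h_max = 5, noise_sd = 0))
  expect_error(compute_E_profile(shallow), "h_min")
})

test_that("median recovered modulus stays within 5% under realistic noise", {
  errs <- vapply(1:25, function(s) {
    fc <- generate_force_curve(curve_spec(1.0, noise_sd = 0.1, seed = 400 + s))
    abs(stats::median(compute_E_profile(fc)$E) - 1.0)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_gt(mean(errs < 0.05), 0.8)
})

test_that("profile averaging works on a common depth grid", {
  mk <- function(E) modulus_profile(seq(10, 100, by = 10), rep(E, 10))
  same <- average_profiles(list(mk(1), mk(1), mk(1)))
  expect_true(all(abs(same$E - 1) < 1e-12))
  avg <- average_profiles(list(mk(0.8), mk(1.0), mk(1.2)))
  expect_true(all(abs(avg$E - 1.0) < 1e-12))
  disjoint <- list(modulus_profile(1:5 * 10, rep(1, 5)),
                   modulus_profile(6:9 * 100, rep(1, 4)))
  expect_error(average_profiles(disjoint), "overlap")
})

test_that("averaging three noisy replicates reduces the modulus error", {
  res <- vapply(1:40, function(s) {
    reps <- lapply(1:3, function(r)
      compute_E_profile(generate_force_curve(
        curve_spec(1.0, noise_sd = 0.1, seed = 9000 + 10 * s + r))))
    avg_err <- abs(mean(average_profiles(reps)$E) - 1)
    rep_errs <- vapply(reps, function(p) abs(mean(p$E) - 1), numeric(1))
    c(beats_worst = avg_err < max(rep_errs), avg = avg_err,
      single = mean(rep_errs))
  }, numeric(3))
  expect_gte(mean(res["beats_worst", ]), 0.9)
  expect_lt(mean(res["avg", ]), mean(res["single", ]))
})

test_that("surface and maximum modulus summarize the profile shape", {
  dec <- modulus_profile(seq(10, 100, 10), seq(1.7, 0.5, length.out = 10))
  s1 <- extract_modulus_summary(dec)
  expect_equal(s1$E_surface, s1$E_max)   # healthy: coincide
  rise <- modulus_profile(seq(10, 100, 10),
                          c(1.14, 1.2, 1.26, 1.3, 1.28, 1.2, 1.1, 1.0, 0.9, 0.8))
  s2 <- extract_modulus_summary(rise)
  expect_gt(s2$E_max, s2$E_surface)
  expect_equal(s2$E_max, 1.3)
  expect_equal(s2$h_at_max, 40)
  one <- extract_modulus_summary(modulus_profile(50, 1.1))
  expect_equal(one$E_surface, one$E_max)
})
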