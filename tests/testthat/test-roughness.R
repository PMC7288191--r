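test_that("plane leveling removes exactly a first-order plane", {
  n <- 16
  plane <- outer(2 * seq_len(n), 3 * seq_len(n), "+") + 7
  lv <- level_height_map(height_map(plane, 10))
  expect_lt(max(abs(lv)), 1e-9)
  # plane + known residual: the residual is recovered
  set.seed(42)
  resid <- matrix(rnorm(n * n), n, n)
  resid <- resid - mean(resid)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  resid <- matrix(stats::lm.fit(cbind(1, ij$i, ij$j),
                                as.vector(resid))$residuals, n, n)
  lv2 <- level_height_map(height_map(resid + plane, 10))
  expect_lt(sqrt(mean((unclass(lv2) - resid)^2)), 1e-9)
  # idempotent; constant maps level to zero without error
  expect_equal(unclass(level_height_map(lv2)), unclass(lv2), tolerance = 1e-12)
  expect_lt(max(abs(level_height_map(height_map(matrix(5, 8, 8), 1)))), 1e-9)
})

test_that("profiles are the rows of the grid with the pixel spacing", {
  m <- matrix(seq_len(12 * 9), 12, 9)
  profs <- extract_profiles(height_map(m, 7))
  expect_length(profs, 12)
  expect_true(all(lengths(profs) == 9))
  expect_equal(as.numeric(profs[[3]]), m[3, ])
  expect_equal(attr(profs[[1]], "spacing"), 7)
})

test_that("Ra and Rp match hand-computed oracles", {
  expect_equal(compute_Ra(c(5, 5, 5, 5)), 0)
  expect_equal(compute_Ra(c(1, -1, 1, -1)), 1)
  expect_equal(compute_Ra(c(0, 1, 2, 3, 4)), 1.2)  # deviations 2,1,0,1,2
  expect_equal(compute_Rp(c(3, 3, 3)), 0)
  expect_equal(compute_Rp(c(0, 1, 2, 3, 4)), 2)    # max 4 - mean 2
  # sampled sine of amplitude A over whole periods
  x <- seq(0, 4 * 2 * pi, length.out = 4 * 64 + 1)[-1]
  expect_equal(compute_Rp(7 * sin(x)), 7, tolerance = 1e-2)
})

test_that("S uses strict local peaks with plateau collapsing", {
  p <- afm_profile(c(0, 1, 0, 1, 0, 1, 0), spacing = 10)
  expect_equal(compute_S(p), 20)                 # peaks at 2,4,6 (1-based)
  expect_equal(count_peaks(p), 3L)
  expect_error(compute_S(afm_profile(1:10, 1)), "peaks")
  # plateau counts once, at its first sample
  q <- afm_profile(c(0, 2, 2, 2, 0, 3, 0), spacing = 1)
  expect_equal(count_peaks(q), 2L)
  expect_equal(compute_S(q), 4)                  # peaks at samples 2 and 6
  # sampled sine, period 100 nm, 10 periods
  spacing <- 1
  x <- seq(0, 1000, by = spacing)
  s <- compute_S(afm_profile(sin(2 * pi * x / 100), spacing))
  expect_equal(s, 100, tolerance = 0.02)
  # the optional height band drops minor peaks
  r <- afm_profile(c(0, 0.1, 0, 5, 0, 0.1, 0, 5, 0), spacing = 1)
  expect_equal(count_peaks(r), 4L)
  expect_equal(compute_S(r, min_prominence = 1), 4)
})

test_that("Sa is the flattened-grid Ra", {
  expect_equal(compute_Sa(height_map(matrix(2, 8, 8), 1)), 0)
  alt <- matrix(rep(c(1, -1), length.out = 8 * 8), 8, 8)
  expect_equal(compute_Sa(height_map(alt, 1)), 1)
  m <- random_map(24, seed = 8)
  z <- as.vector(unclass(m))
  expect_equal(compute_Sa(m), mean(abs(z - mean(z))))
})

test_that("amplitude parameters are translation-invariant and homogeneous", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(64)
    p <- afm_profile(y, spacing = 3)
    c0 <- rnorm(1) * 10
    sc <- runif(1, 0.1, 5)
    expect_equal(compute_Ra(y + c0), compute_Ra(y))
    expect_equal(compute_Rp(y + c0), compute_Rp(y))
    expect_equal(compute_Ra(sc * y), sc * compute_Ra(y))
    expect_equal(compute_Rp(-sc * y), sc * compute_Rp(-y))
    expect_lte(compute_Ra(y), max(abs(y - mean(y))))
    expect_lte(compute_Rp(y), max(y) - min(y))
    # S: invariant under height scaling, equivariant under spacing scaling
    expect_equal(compute_S(afm_profile(sc * y, 3)), compute_S(p))
    expect_equal(compute_S(afm_profile(y, 3 * sc)), sc * compute_S(p))
  }
})

test_that("lacuna detection finds the planted depressions", {
  ps <- 50
  mk <- function(i, j) lacuna_spec(c((i - 0.5) * ps, (j - 0.5) * ps),
                                   c(300, 250), depth = 500)
  sp <- surface_spec(64, 64, ps, target_Ra = 2, seed = 13,
                     lacunae = list(mk(12, 12), mk(32, 40), mk(52, 20)))
  lv <- level_height_map(generate_height_map(sp))
  found <- detect_lacunae(lv, 250)
  expect_identical(nrow(found), 3L)
  expect_true(all(abs(found$depth_nm - 500) < 25))
  # count is non-increasing in the threshold; nothing beyond the max depth
  expect_lte(nrow(detect_lacunae(lv, 400)), 3L)
  expect_identical(nrow(detect_lacunae(lv, 600)), 0L)
  flat <- level_height_map(height_map(matrix(rnorm(32 * 32), 32), ps))
  expect_identical(nrow(detect_lacunae(flat, 250)), 0L)
})

test_that("roughness summaries follow the points x specimens x areas design", {
  mk_records <- function(n_spec) {
    g <- expand.grid(point = 1:5, specimen = seq_len(n_spec),
                     Ar = c("3x3", "9x9", "18x18"))
    set.seed(1)
    data.frame(Ar = g$Ar, Ra = runif(nrow(g), 20, 100),
               Rp = runif(nrow(g), 80, 500), S = runif(nrow(g), 200, 900))
  }
  s25 <- summarize_roughness(mk_records(25))
  expect_identical(sum(s25$n[s25$parameter == "Ra"]), 375L)
  s75 <- summarize_roughness(mk_records(75))
  expect_identical(sum(s75$n[s75$parameter == "Ra"]), 1125L)
  expect_true(all(s25$min <= s25$mean & s25$mean <= s25$max))
  one <- summarize_roughness(data.frame(Ar = "9x9", Ra = 42))
  expect_equal(one$mean, 42)
  expect_equal(one$sd, 0)
  expect_error(summarize_roughness(data.frame(Ar = character(0),
                                              Ra = numeric(0))), "empty")
})

test_that("percent change reproduces the published wear contrasts", {
  expect_identical(percent_change(86, 25), 71)
  expect_identical(percent_change(436, 86), 80)
  expect_identical(percent_change(816, 403), 51)
  expect_identical(percent_change(57, 57), 0)
  expect_error(percent_change(0, 10), "> 0")
  expect_error(percent_change(-5, 10), "> 0")
})

test_that("wear stages tile the worn range with equal widths", {
  b <- wear_boundaries()
  expect_equal(diff(b), rep(12.2, 3), tolerance = 1e-9)
  expect_equal(b, c(24.6, 36.8, 49.0, 61.2), tolerance = 1e-9)
  st <- stage_wear(c(86, 73, 55, 40, 30, 10))
  expect_identical(as.character(st),
                   c("healthy", "healthy", "small", "medium", "heavy",
                     "out_of_range"))
  # ties go to the more-worn stage except the top of the range
  expect_identical(as.character(stage_wear(c(61.2, 49.0, 36.8, 24.6))),
                   c("small", "medium", "heavy", "heavy"))
  expect_error(stage_wear(-1), ">= 0")
})
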