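#' Configuration of a synthetic AFM cartilage study
#'
#' Collects everything the end-to-end study needs: cohort composition,
#' scan areas with their grid geometry, per-group roughness targets, probe
#' constants, indentation ground-truth profiles, wear-stage boundaries and
#' the master seed. Defaults emulate the reference study design: 25 healthy
#' plus 75 osteoarthritic specimens, 5 measurement points per specimen at
#' each of three scan areas (3x3, 9x9, 18x18 um^2), staging on the 9x9
#' scale.
#'
#' @param n_healthy,n_worn cohort sizes.
#' @param areas data frame with columns \code{Ar} (label), \code{nx},
#'   \code{ny}, \code{pixel_size} (nm), \code{corr_len} (nm). The defaults
#'   use 96x96-pixel grids whose pixel sizes realize the three scan areas.
#' @param targets data frame with columns \code{group}, \code{Ar},
#'   \code{Ra}: the ground-truth roughness per group and scan area.
#'   Healthy defaults are the reference healthy means (96/86/28 nm); worn
#'   defaults sit inside the observed worn ranges (65/43/10 nm).
#' @param n_points measurement points (sub-windows) per specimen per area.
#' @param window sub-window edge length in pixels.
#' @param params probe constants (\code{\link{hertz_params}}).
#' @param boundaries wear-stage boundaries, \code{\link{wear_boundaries}}.
#' @param stage_Ar scan-area label used for staging (default \code{"9x9"}).
#' @param seed master integer seed; all per-specimen seeds derive from it.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(n_healthy = 25L, n_worn = 75L,
                         areas = default_areas(),
                         targets = default_targets(),
                         n_points = 5L, window = 32L,
                         params = hertz_params(),
                         boundaries = wear_boundaries(),
                         stage_Ar = "9x9", seed = 1L) {
  stopifnot(is.data.frame(areas),
            all(c("Ar", "nx", "ny", "pixel_size", "corr_len") %in% names(areas)),
            is.data.frame(targets),
            all(c("group", "Ar", "Ra") %in% names(targets)),
            inherits(params, "hertz_params"))
  if (n_healthy + n_worn < 1L) stop("empty cohort")
  structure(list(n_healthy = as.integer(n_healthy),
                 n_worn = as.integer(n_worn), areas = areas,
                 targets = targets, n_points = as.integer(n_points),
                 window = as.integer(window), params = params,
                 boundaries = boundaries, stage_Ar = stage_Ar,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_areas <- function() {
  data.frame(Ar = c("3x3", "9x9", "18x18"),
             nx = 96L, ny = 96L,
             pixel_size = c(3000, 9000, 18000) / 96,
             corr_len = c(3000, 9000, 18000) / 96 * 6)
}

#' @rdname study_config
#' @export
default_targets <- function() {
  data.frame(group = rep(c("healthy", "worn"), each = 3),
             Ar = rep(c("18x18", "9x9", "3x3"), 2),
             Ra = c(96, 86, 28, 65, 43, 10))
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("Study config: %d healthy + %d worn specimens, %d points x %d areas, seed %d\n",
              x$n_healthy, x$n_worn, x$n_points, nrow(x$areas), x$seed))
  invisible(x)
}

# deterministic per-(specimen, area, point) seed derived from the master
derive_seed <- function(master, specimen, area, point = 0L) {
  (master * 7919L + specimen * 1009L + area * 131L + point * 17L) %% 2147483647L
}

#' Run the synthetic roughness study end to end
#'
#' For every specimen and scan area a surface is generated at the group's
#' target roughness, leveled, and sampled at \code{n_points} non-overlapping
#' sub-windows (the "measurement points"); Ra, Rp and S are computed per
#' point, aggregated per group and area, compared between groups as percent
#' changes, and each specimen is assigned a wear stage from its mean Ra on
#' the staging scan area. Fully deterministic for a fixed config.
#'
#' @param config a \code{\link{study_config}}.
#' @return An object of class \code{"study_report"} with elements
#'   \code{records} (one row per specimen x area x point),
#'   \code{summary_healthy}, \code{summary_worn}
#'   (\code{\link{summarize_roughness}} tables), \code{percent_change}
#'   (healthy mean vs worn extreme per parameter and area), \code{stages}
#'   (per-specimen stage from mean Ra at the staging area) and
#'   \code{counts}.
#' @export
run_roughness_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  groups <- c(rep("healthy", config$n_healthy), rep("worn", config$n_worn))
  if (!length(groups)) stop("empty cohort")
  recs <- vector("list", length(groups) * nrow(config$areas))
  k <- 0L
  for (s in seq_along(groups)) {
    for (a in seq_len(nrow(config$areas))) {
      ar <- config$areas[a, ]
      tgt <- config$targets$Ra[config$targets$group == groups[s] &
                                 config$targets$Ar == ar$Ar]
      if (length(tgt) != 1L)
        stop(sprintf("no unique Ra target for group '%s', area '%s'",
                     groups[s], ar$Ar))
      sp <- surface_spec(ar$nx, ar$ny, ar$pixel_size, tgt,
                         correlation_length = ar$corr_len,
                         seed = derive_seed(config$seed, s, a))
      map <- level_height_map(generate_height_map(sp))
      wins <- sample_windows(ar$nx, ar$ny, config$window, config$n_points,
                             seed = derive_seed(config$seed, s, a, 1L))
      pts <- lapply(seq_len(nrow(wins)), function(p) {
        w <- unclass(map)[wins$i0[p]:(wins$i0[p] + config$window - 1L),
                          wins$j0[p]:(wins$j0[p] + config$window - 1L)]
        cbind(specimen = s, group = groups[s], Ar = ar$Ar, point = p,
              roughness_point(height_map(w, ar$pixel_size, ar$Ar)))
      })
      k <- k + 1L
      recs[[k]] <- do.call(rbind, pts)
    }
  }
  records <- do.call(rbind, recs)
  sum_h <- summarize_roughness(records[records$group == "healthy", ],
                               params = c("Ra", "Rp", "S"))
  sum_w <- summarize_roughness(records[records$group == "worn", ],
                               params = c("Ra", "Rp", "S"))
  pc <- merge(as.data.frame(sum_h)[, c("Ar", "parameter", "mean")],
              as.data.frame(sum_w)[, c("Ar", "parameter", "min")],
              by = c("Ar", "parameter"))
  names(pc)[3:4] <- c("healthy_mean", "worn_extreme")
  pc$percent_change <- mapply(percent_change, pc$healthy_mean,
                              pc$worn_extreme)
  ra9 <- records[records$Ar == config$stage_Ar, ]
  mean_Ra <- tapply(ra9$Ra, ra9$specimen, mean)
  stages <- data.frame(specimen = as.integer(names(mean_Ra)),
                       group = groups[as.integer(names(mean_Ra))],
                       mean_Ra = as.numeric(mean_Ra))
  stages$stage <- as.character(stage_wear(stages$mean_Ra, config$boundaries))
  structure(list(records = records, summary_healthy = sum_h,
                 summary_worn = sum_w, percent_change = pc,
                 stages = stages[order(stages$specimen), ],
                 counts = c(healthy = sum(records$group == "healthy"),
                            worn = sum(records$group == "worn"))),
            class = "study_report")
}

# n non-overlapping square sub-windows: the grid is partitioned into
# disjoint tiles at least `window` wide, n distinct tiles are drawn and
# the window is jittered uniformly within each tile's slack -- seeded,
# uniform placement that cannot deadlock
sample_windows <- function(nx, ny, window, n, seed) {
  if (window > nx || window > ny)
    stop("sub-window larger than the grid")
  ki <- nx %/% window; kj <- ny %/% window
  if (ki * kj < n)
    stop("could not place non-overlapping measurement windows: grid fits ",
         ki * kj, " windows, ", n, " requested")
  ti <- nx %/% ki; tj <- ny %/% kj   # tile sizes (>= window)
  with_seed(seed, {
    tiles <- sample.int(ki * kj, n)
    i_t <- (tiles - 1L) %% ki
    j_t <- (tiles - 1L) %/% ki
    data.frame(
      i0 = i_t * ti + sample.int(ti - window + 1L, n, replace = TRUE),
      j0 = j_t * tj + sample.int(tj - window + 1L, n, replace = TRUE))
  })
}

#' @export
print.study_report <- function(x, digits = 4, ...) {
  cat("AFM cartilage study report\n")
  if (!is.null(x$counts))
    cat(sprintf("  roughness records: %d healthy, %d worn\n",
                x$counts[["healthy"]], x$counts[["worn"]]))
  if (!is.null(x$percent_change)) {
    cat("  percent change (healthy mean vs worn extreme):\n")
    print.data.frame(x$percent_change, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$stages)) {
    cat("  wear stages:\n")
    print(table(x$stages$group, x$stages$stage))
  }
  if (!is.null(x$modulus)) {
    cat("  modulus summaries (per stage and layer):\n")
    print.data.frame(x$modulus, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Ground-truth E(h) profiles per wear stage and layer
#'
#' Piecewise-linear depth profiles of Young's modulus emulating the
#' observed behaviour: on the healthy surface layer E declines monotonically
#' from 1.7 to 0.5 MPa; on worn surface layers E first rises from its
#' surface value to an interior maximum (1.14 to 1.3, 1.02 to 1.2,
#' 0.82 to 1.2 MPa for the small/medium/heavy stages) before decreasing;
#' subsurface cross-section layers decline monotonically at every stage.
#'
#' @param stage one of \code{"healthy"}, \code{"small"}, \code{"medium"},
#'   \code{"heavy"}.
#' @param layer 1 (surface) or 2-3 (cross-sections).
#' @param h_max depth range end, nm.
#' @return A vectorized function h (nm) -> E (MPa).
#' @export
stage_E_profile <- function(stage = c("healthy", "small", "medium", "heavy"),
                            layer = 1L, h_max = 200) {
  stage <- match.arg(stage)
  surf <- list(healthy = c(1.7, NA, 0.5),   # monotone decline
               small = c(1.14, 1.3, 0.9),
               medium = c(1.02, 1.2, 0.85),
               heavy = c(0.82, 1.2, 0.8))
  cross <- list(healthy = c(1.7, 0.5), small = c(1.2, 0.65),
                medium = c(1.0, 0.6), heavy = c(0.8, 0.6))
  if (layer == 1L) {
    v <- surf[[stage]]
    if (is.na(v[2])) {
      function(h) v[1] + (v[3] - v[1]) * pmin(pmax(h / h_max, 0), 1)
    } else {
      hp <- 0.4 * h_max  # depth of the interior maximum
      function(h) {
        h <- pmin(pmax(h, 0), h_max)
        ifelse(h <= hp, v[1] + (v[2] - v[1]) * h / hp,
               v[2] + (v[3] - v[2]) * (h - hp) / (h_max - hp))
      }
    }
  } else {
    v <- cross[[stage]]
    function(h) v[1] + (v[2] - v[1]) * pmin(pmax(h / h_max, 0), 1)
  }
}

#' Run the synthetic indentation study end to end
#'
#' For every wear stage and layer (1 = surface, 2-3 = cross-sections) a
#' site is indented in \code{n_repeats} replicate force curves generated
#' from the stage's ground-truth E(h) profile; replicates are averaged on
#' a common depth grid and summarized as surface and maximum modulus.
#' Fewer than 3 repeats per site triggers a warning and averages what is
#' available.
#'
#' @param config a \code{\link{study_config}}.
#' @param stages wear stages to simulate.
#' @param layers layers per stage.
#' @param n_repeats replicate indentations per site (reference protocol: 3).
#' @param noise_sd deflection noise, nm.
#' @param h_max maximum indentation depth, nm.
#' @return A \code{"study_report"} whose \code{modulus} element has one row
#'   per stage x layer: \code{E_surface}, \code{E_max}, \code{h_at_max}
#'   (from the averaged profile) and \code{E_deep} (modulus at the deepest
#'   point). \code{profiles} holds the averaged \code{modulus_profile}s.
#' @export
run_indentation_study <- function(config,
                                  stages = c("healthy", "small", "medium",
                                             "heavy"),
                                  layers = 1:3, n_repeats = 3L,
                                  noise_sd = 0.1, h_max = 200) {
  stopifnot(inherits(config, "study_config"))
  if (n_repeats < 3L)
    warning("fewer than 3 repeats per site; averaging available repeats")
  rows <- list(); profs <- list()
  for (si in seq_along(stages)) {
    for (ly in layers) {
      Efun <- stage_E_profile(stages[si], ly, h_max)
      reps <- lapply(seq_len(n_repeats), function(r) {
        cs <- curve_spec(Efun, params = config$params, h_max = h_max,
                         noise_sd = noise_sd,
                         seed = derive_seed(config$seed, si, ly, r))
        compute_E_profile(generate_force_curve(cs))
      })
      avg <- average_profiles(reps)
      ms <- extract_modulus_summary(avg)
      key <- sprintf("%s.L%d", stages[si], ly)
      profs[[key]] <- avg
      rows[[key]] <- data.frame(stage = stages[si], layer = ly,
                                E_surface = ms$E_surface, E_max = ms$E_max,
                                h_at_max = ms$h_at_max,
                                E_deep = avg$E[nrow(avg)])
    }
  }
  structure(list(modulus = do.call(rbind, c(rows, make.row.names = FALSE)),
                 profiles = profs),
            class = "study_report")
}
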