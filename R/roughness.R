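#' Profile roughness parameters Ra, Rp and S
#'
#' Amplitude and spacing parameters of a leveled line profile, as used in
#' AFM surface metrology of cartilage:
#' \itemize{
#'   \item \code{compute_Ra}: arithmetic average of absolute deviations from
#'     the profile mean, \eqn{Ra = mean(|y_i - \bar y|)} (nm).
#'   \item \code{compute_Rp}: maximum peak height above the profile mean,
#'     \eqn{Rp = max(y_i) - \bar y} (nm).
#'   \item \code{compute_S}: mean spacing between consecutive local peaks
#'     (nm). A local peak is a sample strictly greater than both immediate
#'     neighbours; a plateau (run of equal samples higher than both
#'     flanks) collapses to its first sample. An optional height
#'     discrimination band \code{min_prominence} ignores peaks that do not
#'     rise above the profile mean by that amount; it defaults to off
#'     (0 nm).
#' }
#' The mean line is the plain profile mean (no per-profile refit); level the
#' parent map first with \code{\link{level_height_map}}.
#'
#' @param p an \code{\link{afm_profile}} (any numeric vector is accepted and
#'   treated as a profile for Ra/Rp; S needs a spacing, defaulting to 1 nm).
#' @param min_prominence height band (nm) a peak must clear above the mean
#'   to count for S; default 0 (off).
#' @return Ra, Rp: nm. \code{compute_S}: nm; it is an error if the profile
#'   has fewer than two local peaks (S is undefined).
#' @examples
#' p <- afm_profile(c(0, 1, 0, 1, 0, 1, 0), spacing = 10)
#' compute_Ra(p); compute_Rp(p); compute_S(p)  # S = 20 nm
#' @export
compute_Ra <- function(p) {
  y <- as.numeric(p)
  if (length(y) < 2L) stop("profile must have >= 2 samples")
  mean(abs(y - mean(y)))
}

#' @rdname compute_Ra
#' @export
compute_Rp <- function(p) {
  y <- as.numeric(p)
  if (length(y) < 2L) stop("profile must have >= 2 samples")
  max(y) - mean(y)
}

# Indices of strict local maxima, plateaus collapsed to their first sample.
local_peak_indices <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  # run-length collapse so plateaus compare against their flanking runs
  r <- rle(y)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(v)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_peak <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  starts[mid][is_peak]
}

#' @rdname compute_Ra
#' @export
compute_S <- function(p, min_prominence = 0) {
  y <- as.numeric(p)
  spacing <- attr(p, "spacing")
  if (is.null(spacing)) spacing <- 1
  idx <- local_peak_indices(y)
  if (min_prominence > 0)
    idx <- idx[y[idx] - mean(y) >= min_prominence]
  if (length(idx) < 2L)
    stop("S undefined: profile has fewer than 2 local peaks")
  mean(diff(idx)) * spacing
}

#' Count local peaks of a profile
#'
#' Companion to \code{\link{compute_S}}; uses the same strict-maximum,
#' plateau-collapsing peak definition.
#'
#' @inheritParams compute_Ra
#' @return integer number of local peaks.
#' @export
count_peaks <- function(p) length(local_peak_indices(as.numeric(p)))

#' Areal roughness parameter Sa
#'
#' Three-dimensional analogue of Ra over a full (leveled) height map:
#' \eqn{Sa = mean(|z_{ij} - \bar z|)} in nm. Equals \code{compute_Ra}
#' applied to the flattened grid.
#'
#' @param map an \code{\link{height_map}}, normally leveled.
#' @return Sa in nm.
#' @export
compute_Sa <- function(map) {
  stopifnot(inherits(map, "afm_height_map"))
  z <- as.vector(unclass(map))
  mean(abs(z - mean(z)))
}

#' Roughness parameters of one measurement point
#'
#' Convenience wrapper: levels a height map, extracts its row profiles and
#' returns the grand means of Ra, Rp and (where defined) S over rows,
#' plus the mean peak count — the per-point record the study pipeline
#' aggregates.
#'
#' @param map an \code{\link{height_map}}.
#' @return A one-row data frame with columns \code{Ra}, \code{Rp}, \code{S},
#'   \code{n_peaks}; \code{S} is \code{NA} if no row has two peaks.
#' @export
roughness_point <- function(map) {
  lv <- level_height_map(map)
  profs <- extract_profiles(lv)
  S_vals <- vapply(profs, function(p)
    tryCatch(compute_S(p), error = function(e) NA_real_), numeric(1))
  data.frame(
    Ra = mean(vapply(profs, compute_Ra, numeric(1))),
    Rp = mean(vapply(profs, compute_Rp, numeric(1))),
    S = if (all(is.na(S_vals))) NA_real_ else mean(S_vals, na.rm = TRUE),
    n_peaks = mean(vapply(profs, count_peaks, numeric(1)))
  )
}

#' Detect lacunae (deep depressions) in a leveled height map
#'
#' Chondrocyte lacunae appear in cartilage topography as elliptical
#' depressions (roughly 500 nm deep on worn surfaces, over 2 um on healthy
#' ones). Pixels deeper than \code{depth_threshold} below the median surface
#' are grouped into 8-connected regions; each region is reported with its
#' area-weighted centroid, area and maximum depth.
#'
#' @param map a leveled \code{\link{height_map}}.
#' @param depth_threshold depth below the median surface (nm, > 0) for a
#'   pixel to count as lacunar.
#' @return A data frame with one row per region and columns \code{id},
#'   \code{x_nm}, \code{y_nm} (centroid), \code{area_nm2},
#'   \code{depth_nm} (maximum depth, positive). Zero rows when nothing is
#'   deeper than the threshold; the count is non-increasing in the
#'   threshold.
#' @export
detect_lacunae <- function(map, depth_threshold) {
  stopifnot(inherits(map, "afm_height_map"))
  stop_if_not_scalar_num(depth_threshold, "depth_threshold", positive = TRUE)
  ps <- attr(map, "pixel_size")
  z <- unclass(map)
  depth <- stats::median(z) - z          # positive where the surface dips
  mask <- depth > depth_threshold
  empty <- data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                      area_nm2 = numeric(0), depth_nm = numeric(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(id = as.integer(id),
               x_nm = mean(w[, 1]) * ps,
               y_nm = mean(w[, 2]) * ps,
               area_nm2 = nrow(w) * ps^2,
               depth_nm = max(depth[w]))
  })
  do.call(rbind, out)
}

#' Summarize roughness results by scan area
#'
#' Aggregates per-point roughness records into a Table-1/2-style summary:
#' mean, sd (n-1 denominator), min and max of each parameter per scan-area
#' group, with the record count. A single record per group yields
#' sd = 0 by convention.
#'
#' @param results data frame with columns \code{Ar} (scan-area label) and
#'   one column per roughness parameter (e.g. \code{Ra}, \code{Rp},
#'   \code{S}).
#' @param params parameter columns to summarize; defaults to all numeric
#'   columns other than \code{Ar}.
#' @return An object of class \code{"roughness_summary"}: a data frame with
#'   columns \code{Ar}, \code{parameter}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{n}.
#' @export
summarize_roughness <- function(results, params = NULL) {
  stopifnot(is.data.frame(results), "Ar" %in% names(results))
  if (nrow(results) == 0L) stop("empty results: nothing to summarize")
  if (is.null(params))
    params <- setdiff(names(results)[vapply(results, is.numeric, logical(1))],
                      c("Ar", "specimen", "point"))
  groups <- split(results, results$Ar)
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(params, function(pm) {
      v <- df[[pm]]
      v <- v[!is.na(v)]
      if (!length(v)) stop(sprintf("group '%s' has no data for '%s'", g, pm))
      data.frame(Ar = g, parameter = pm, mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 min = min(v), max = max(v), n = length(v))
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roughness_summary", "data.frame")
  out
}

#' @export
print.roughness_summary <- function(x, digits = 4, ...) {
  cat("Roughness summary (per scan area):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Percent change of a roughness parameter relative to healthy
#'
#' The maximal wear-related change of a parameter is reported as
#' \eqn{100 (healthy - worn) / healthy}, rounded to the nearest integer
#' percent. With the healthy means and the worn extremes of the printed
#' tables at the 9x9 um^2 scan area this gives 71\%, 80\% and 51\% for Ra,
#' Rp and S.
#'
#' @param healthy_mean healthy-group mean (nm, > 0).
#' @param worn_extreme worn-group extreme value (nm).
#' @param round round to the nearest integer percent (default TRUE, the
#'   reporting convention).
#' @return percent change (numeric).
#' @examples
#' percent_change(86, 25)   # 71
#' percent_change(436, 86)  # 80
#' percent_change(816, 403) # 51
#' @export
percent_change <- function(healthy_mean, worn_extreme, round = TRUE) {
  stop_if_not_scalar_num(healthy_mean, "healthy_mean")
  if (healthy_mean <= 0) stop("'healthy_mean' must be > 0")
  stop_if_not_scalar_num(worn_extreme, "worn_extreme")
  pc <- 100 * (healthy_mean - worn_extreme) / healthy_mean
  if (round) round(pc) else pc
}

#' Wear-stage boundaries
#'
#' The worn-cartilage Ra range [24.6, 61.2] nm is tripartitioned into three
#' equal-width subranges of 12.2 nm; the interior boundaries are 36.8 and
#' 49.0 nm. Ra above the range is healthy; below it, out of range.
#'
#' @param lo,hi ends of the worn Ra range (nm); defaults 24.6 and 61.2.
#' @return Numeric vector of the four boundaries \code{c(lo, lo+w, lo+2w, hi)}
#'   with \code{w = (hi-lo)/3}.
#' @export
wear_boundaries <- function(lo = 24.6, hi = 61.2) {
  stopifnot(hi > lo)
  w <- (hi - lo) / 3
  c(lo, lo + w, lo + 2 * w, hi)
}

#' Assign a wear stage from Ra
#'
#' Stages partition the worn Ra range into equal-width subranges
#' (see \code{\link{wear_boundaries}}): \code{healthy} above 61.2 nm,
#' \code{small} in (49.0, 61.2], \code{medium} in (36.8, 49.0],
#' \code{heavy} in [24.6, 36.8], and \code{out_of_range} below 24.6 nm.
#' Boundary values fall to the lower (more worn) stage, except the top of
#' the range which closes at 61.2.
#'
#' @param Ra arithmetic-mean roughness in nm (>= 0); vectorized.
#' @param boundaries stage boundaries as returned by
#'   \code{\link{wear_boundaries}}.
#' @return An object of class \code{"wear_stage"}: a factor with levels
#'   \code{out_of_range, heavy, medium, small, healthy} and the boundary
#'   vector as attribute \code{Ra_bounds}.
#' @examples
#' stage_wear(c(86, 55, 40, 30, 10))
#' @export
stage_wear <- function(Ra, boundaries = wear_boundaries()) {
  if (any(!is.finite(Ra)) || any(Ra < 0)) stop("'Ra' must be >= 0 and finite")
  b <- boundaries
  lab <- ifelse(Ra > b[4], "healthy",
         ifelse(Ra > b[3], "small",
         ifelse(Ra > b[2], "medium",
         ifelse(Ra >= b[1], "heavy", "out_of_range"))))
  structure(factor(lab, levels = c("out_of_range", "heavy", "medium",
                                   "small", "healthy")),
            Ra_bounds = b, class = c("wear_stage", "factor"))
}

#' @export
print.wear_stage <- function(x, ...) {
  b <- attr(x, "Ra_bounds")
  print(factor(x, levels = levels(x)))
  cat(sprintf("stage boundaries (nm): %s\n", paste(b, collapse = " / ")))
  invisible(x)
}
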