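#' Hertz contact parameters of an AFM probe
#'
#' The constants entering the Hertz sphere model for AFM indentation:
#' Poisson's ratio of the sample V, cantilever stiffness k (N/m) and tip
#' radius R (nm). The defaults are those of a CSC38 silicon probe on
#' cartilage: V = 0.5 (incompressible), k = 0.08 N/m, R = 30 nm.
#'
#' @param V Poisson's ratio, 0 <= V < 1.
#' @param k cantilever stiffness in N/m (> 0).
#' @param R tip radius in nm (> 0).
#' @return An object of class \code{"hertz_params"} (named list).
#' @export
hertz_params <- function(V = 0.5, k = 0.08, R = 30) {
  stop_if_not_scalar_num(V, "V"); stop_if_not_scalar_num(k, "k", TRUE)
  stop_if_not_scalar_num(R, "R", TRUE)
  if (V < 0 || V >= 1) stop("'V' must satisfy 0 <= V < 1")
  structure(list(V = V, k = k, R = R), class = "hertz_params")
}

#' @export
print.hertz_params <- function(x, ...) {
  cat(sprintf("Hertz probe parameters: V = %g, k = %g N/m, R = %g nm\n",
              x$V, x$k, x$R))
  invisible(x)
}

#' AFM force curve
#'
#' The approach segment of an AFM force-spectroscopy record: vertical stage
#' position Zpos (nm, strictly increasing) paired with cantilever deflection
#' Zdefl (nm), with the probe constants attached. \code{Z0} is the baseline
#' deflection reference subtracted before analysis.
#'
#' @param Zpos,Zdefl numeric vectors of equal length >= 8, nm.
#' @param params a \code{\link{hertz_params}} object.
#' @param Z0 baseline deflection reference in nm (default 0).
#' @param true_contact optional integer, the generator's ground-truth
#'   contact index (kept for validation of detectors).
#' @return An object of class \code{"afm_force_curve"}.
#' @export
force_curve <- function(Zpos, Zdefl, params = hertz_params(), Z0 = 0,
                        true_contact = NA_integer_) {
  Zpos <- as.numeric(Zpos); Zdefl <- as.numeric(Zdefl)
  if (length(Zpos) != length(Zdefl) || length(Zpos) < 8L)
    stop("'Zpos' and 'Zdefl' must have equal length >= 8")
  if (any(diff(Zpos) <= 0)) stop("'Zpos' must be strictly increasing")
  stopifnot(inherits(params, "hertz_params"))
  structure(list(Zpos = Zpos, Zdefl = Zdefl, params = params, Z0 = Z0,
                 true_contact = as.integer(true_contact)),
            class = "afm_force_curve")
}

#' @export
print.afm_force_curve <- function(x, ...) {
  cat(sprintf("AFM force curve: %d samples, Zpos [%.3g, %.3g] nm, max Zdefl %.3g nm\n",
              length(x$Zpos), min(x$Zpos), max(x$Zpos), max(x$Zdefl)))
  print(x$params)
  invisible(x)
}

#' @export
plot.afm_force_curve <- function(x, ...) {
  graphics::plot(x$Zpos, x$Zdefl, type = "l", xlab = "Zpos [nm]",
                 ylab = "Zdefl [nm]", main = "Force curve (approach)", ...)
  if (!is.na(x$true_contact))
    graphics::abline(v = x$Zpos[x$true_contact], lty = 2, col = "red")
  invisible(x)
}

#' Detect the tip-sample contact point of a force curve
#'
#' The pre-contact baseline mean and noise sd are estimated from the first
#' \code{baseline_fraction} of samples; the contact point is the first index
#' whose baseline-subtracted deflection exceeds \code{noise_mult} times the
#' baseline sd and stays above it for \code{persistence} consecutive
#' samples. On a noiseless curve (sd = 0) this is the first strictly
#' positive deflection.
#'
#' @param curve an \code{\link{force_curve}}.
#' @param noise_mult threshold in baseline-sd units (default 3).
#' @param baseline_fraction fraction of leading samples treated as baseline
#'   (default 0.2).
#' @param persistence number of consecutive above-threshold samples required
#'   (default 3).
#' @return A list with \code{index} (first persistent crossing),
#'   \code{touch} (last sample still at the baseline before the crossing;
#'   the sample used to re-reference the stage position), \code{baseline}
#'   (estimated baseline deflection, nm) and \code{sd} (baseline noise,
#'   nm). Errors if no index qualifies ("no contact detected").
#' @export
detect_contact_point <- function(curve, noise_mult = 3,
                                 baseline_fraction = 0.2, persistence = 3L) {
  stopifnot(inherits(curve, "afm_force_curve"))
  n <- length(curve$Zdefl)
  nb <- max(3L, floor(baseline_fraction * n))
  base <- curve$Zdefl[seq_len(nb)]
  mu <- mean(base)
  sdv <- stats::sd(base)
  thr <- mu + noise_mult * sdv
  above <- curve$Zdefl > thr
  # first index from which `persistence` consecutive samples stay above
  ok <- which(above)
  cand <- ok[vapply(ok, function(i)
    i + persistence - 1L <= n && all(above[i:(i + persistence - 1L)]),
    logical(1))]
  if (!length(cand)) stop("no contact detected")
  idx <- cand[1L]
  # touch point: last sample whose deflection is still within one noise sd
  # of the baseline -- where the tip actually met the surface
  at_base <- which(curve$Zdefl[seq_len(idx)] <= mu + sdv)
  touch <- if (length(at_base)) at_base[length(at_base)] else idx
  list(index = idx, touch = touch, baseline = mu, sd = sdv)
}

#' Indentation depth from a force curve
#'
#' After re-referencing stage position and deflection to the contact point,
#' the indentation depth of each post-contact sample is
#' \eqn{h = Zpos - Zdefl} (nm): the stage travel not taken up by cantilever
#' bending.
#'
#' @param curve an \code{\link{force_curve}}.
#' @param contact contact index, e.g. from
#'   \code{\link{detect_contact_point}}; the sample at which tip and surface
#'   meet.
#' @param baseline baseline deflection (nm) subtracted from Zdefl before
#'   re-referencing; default the deflection at the contact sample.
#' @param tol largest tolerated negative depth (nm) before the contact
#'   point is declared inconsistent; small negatives within \code{tol}
#'   (deflection noise) are clamped to zero. Default \code{1e-9}.
#' @return A list with vectors \code{h} (nm, post-contact depths, >= 0),
#'   \code{Zdefl} (re-referenced deflections) and \code{index} (original
#'   sample indices). Negative depths beyond \code{tol} signal a bad
#'   contact point and raise an error.
#' @export
compute_indentation_depth <- function(curve, contact, baseline = NULL,
                                      tol = 1e-9) {
  stopifnot(inherits(curve, "afm_force_curve"))
  n <- length(curve$Zpos)
  if (!is.numeric(contact) || contact < 1L || contact > n)
    stop("invalid contact index")
  contact <- as.integer(contact)
  if (is.null(baseline)) baseline <- curve$Zdefl[contact]
  idx <- contact:n
  zp <- curve$Zpos[idx] - curve$Zpos[contact]
  zd <- curve$Zdefl[idx] - baseline
  h <- zp - zd
  if (any(h < -tol))
    stop("negative indentation depth: contact point is inconsistent")
  list(h = pmax(h, 0), Zdefl = zd, index = idx)
}

# nm -> m
.NM <- 1e-9

#' Pointwise Young's modulus from the Hertz sphere model
#'
#' For a spherical tip of radius R indenting an elastic half-space, the
#' Hertz load is \eqn{F = (4/3) E/(1-V^2) \sqrt{R} h^{3/2}} with
#' \eqn{F = k\,Zdefl}; solving for the modulus,
#' \deqn{E = \frac{3 (1-V^2)\, k\, Zdefl}{4 \sqrt{R}\, h^{3/2}}.}
#' Inputs are nm and N/m; the evaluation converts internally to SI and
#' returns E in MPa. Depths below \code{h_min} are rejected (the
#' \eqn{h^{-3/2}} factor diverges at contact).
#'
#' @param Zdefl cantilever deflection in nm (>= 0); vectorized.
#' @param h indentation depth in nm (>= \code{h_min}); vectorized.
#' @param params a \code{\link{hertz_params}} object.
#' @param h_min smallest admissible depth in nm (default 10).
#' @return Young's modulus in MPa.
#' @examples
#' compute_E_point(Zdefl = 10, h = 100, hertz_params())  # ~0.0822 MPa
#' @export
compute_E_point <- function(Zdefl, h, params = hertz_params(), h_min = 10) {
  stopifnot(inherits(params, "hertz_params"))
  if (any(!is.finite(Zdefl)) || any(Zdefl < 0))
    stop("'Zdefl' must be finite and >= 0")
  if (any(!is.finite(h)) || any(h < h_min))
    stop(sprintf("'h' must be >= h_min (%g nm)", h_min))
  F_N <- params$k * (Zdefl * .NM)          # N
  R_m <- params$R * .NM
  h_m <- h * .NM
  E_Pa <- 3 * (1 - params$V^2) * F_N / (4 * sqrt(R_m) * h_m^1.5)
  E_Pa / 1e6
}

#' Depth-resolved modulus profile
#'
#' A sequence of (depth h, modulus E) pairs extracted from one force curve:
#' the relationship E(h) between Young's modulus and penetration depth.
#'
#' @param h depths in nm, strictly increasing, all >= \code{h_min}.
#' @param E moduli in MPa, all > 0.
#' @param h_min smallest valid depth (nm).
#' @return An object of class \code{"modulus_profile"} (data frame with
#'   columns \code{h}, \code{E} and attribute \code{h_min}).
#' @export
modulus_profile <- function(h, E, h_min = min(h)) {
  h <- as.numeric(h); E <- as.numeric(E)
  if (length(h) != length(E) || length(h) < 1L)
    stop("'h' and 'E' must be non-empty and of equal length")
  if (any(diff(h) <= 0)) stop("'h' must be strictly increasing")
  if (any(E <= 0)) stop("'E' must be > 0")
  structure(data.frame(h = h, E = E), h_min = h_min,
            class = c("modulus_profile", "data.frame"))
}

#' @export
print.modulus_profile <- function(x, ...) {
  cat(sprintf("Modulus profile: %d depths in [%.3g, %.3g] nm, E in [%.3g, %.3g] MPa\n",
              nrow(x), min(x$h), max(x$h), min(x$E), max(x$E)))
  invisible(x)
}

#' @export
plot.modulus_profile <- function(x, ...) {
  graphics::plot(x$h, x$E, type = "b", xlab = "h [nm]", ylab = "E [MPa]",
                 main = "Young's modulus vs indentation depth", ...)
  invisible(x)
}

#' Extract the E(h) profile from a force curve
#'
#' Detects the contact point (unless given), re-references the curve,
#' computes indentation depths and applies the Hertz point formula to every
#' post-contact sample with depth at least \code{h_min}.
#'
#' @param curve an \code{\link{force_curve}}.
#' @param h_min smallest depth kept, nm (default 10); guards the Hertz
#'   divergence at contact.
#' @param contact optional known contact index; when \code{NULL} it is
#'   detected with \code{\link{detect_contact_point}}.
#' @param ... passed to \code{\link{detect_contact_point}}.
#' @return A \code{\link{modulus_profile}}. Errors when no post-contact
#'   sample reaches \code{h_min}.
#' @export
compute_E_profile <- function(curve, h_min = 10, contact = NULL, ...) {
  stopifnot(inherits(curve, "afm_force_curve"))
  if (is.null(contact)) {
    det <- detect_contact_point(curve, ...)
    dep <- compute_indentation_depth(curve, det$touch, baseline = det$baseline,
                                     tol = max(1e-9, 8 * det$sd))
  } else {
    dep <- compute_indentation_depth(curve, contact)
  }
  keep <- dep$h >= h_min & dep$Zdefl > 0
  if (!any(keep)) stop("no post-contact samples with h >= h_min")
  h <- dep$h[keep]; zd <- dep$Zdefl[keep]
  o <- order(h)
  h <- h[o]; zd <- zd[o]
  dup <- duplicated(h)
  h <- h[!dup]; zd <- zd[!dup]
  modulus_profile(h, compute_E_point(zd, h, curve$params, h_min = h_min),
                  h_min = h_min)
}

#' Average replicate modulus profiles on a common depth grid
#'
#' Each surface site is indented in (typically three) replicate
#' measurements; the E(h) profiles are averaged pointwise after linear
#' interpolation onto a common depth grid spanning the overlap of the
#' replicate depth ranges.
#'
#' @param profiles list of \code{\link{modulus_profile}} objects (>= 1).
#' @param n_grid number of points of the common grid (default 50).
#' @return A \code{\link{modulus_profile}} on the common grid. Errors when
#'   the depth ranges do not overlap.
#' @export
average_profiles <- function(profiles, n_grid = 50L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "modulus_profile")))
  lo <- max(vapply(profiles, function(p) min(p$h), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$h), numeric(1)))
  if (hi <= lo) stop("profiles have no overlapping depth range")
  grid <- seq(lo, hi, length.out = n_grid)
  Em <- vapply(profiles,
               function(p) stats::approx(p$h, p$E, xout = grid)$y,
               numeric(n_grid))
  modulus_profile(grid, rowMeans(as.matrix(Em)),
                  h_min = min(vapply(profiles, attr, numeric(1), "h_min")))
}

#' Surface and maximum modulus of a profile
#'
#' Summary pair used to relate mechanics to wear: \code{E_surface} is the
#' modulus at the smallest depth of the profile; \code{E_max} the maximum
#' over the profile with the depth where it occurs. For a monotone
#' decreasing profile (healthy cartilage) the two coincide; worn surfaces
#' show E rising to an interior maximum first.
#'
#' @param profile a \code{\link{modulus_profile}}.
#' @return An object of class \code{"modulus_summary"}: list with
#'   \code{E_surface}, \code{E_max} (MPa) and \code{h_at_max} (nm).
#' @export
extract_modulus_summary <- function(profile) {
  stopifnot(inherits(profile, "modulus_profile"), nrow(profile) >= 1L)
  i <- which.max(profile$E)
  structure(list(E_surface = profile$E[1L], E_max = profile$E[i],
                 h_at_max = profile$h[i]),
            class = "modulus_summary")
}

#' @export
print.modulus_summary <- function(x, ...) {
  cat(sprintf("E_surface = %.4g MPa; E_max = %.4g MPa at h = %.4g nm\n",
              x$E_surface, x$E_max, x$h_at_max))
  invisible(x)
}
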