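#' Specification of a synthetic rough surface
#'
#' Describes a cartilage-like AFM surface to simulate: an isotropic
#' correlated random texture of prescribed roughness, optional elliptical
#' lacunae (depressions) and an optional instrumental tilt plane.
#'
#' @param nx,ny grid dimensions in pixels (>= 8).
#' @param pixel_size lateral sampling in nm/pixel.
#' @param target_Ra desired grand mean of the row-profile Ra, nm (> 0).
#' @param correlation_length lateral correlation length of the texture in nm
#'   (>= 2 * pixel_size); the lag at which the autocorrelation falls to 1/e.
#' @param tilt numeric length-2, plane slopes (nm/pixel) along rows and
#'   columns, added last.
#' @param lacunae list of \code{\link{lacuna_spec}} objects.
#' @param seed integer seed; identical specs yield bitwise-identical maps.
#' @return An object of class \code{"surface_spec"}.
#' @export
surface_spec <- function(nx, ny, pixel_size, target_Ra,
                         correlation_length = 4 * pixel_size,
                         tilt = c(0, 0), lacunae = list(), seed = 1L) {
  stopifnot(nx >= 8, ny >= 8, length(tilt) == 2)
  stop_if_not_scalar_num(pixel_size, "pixel_size", TRUE)
  stop_if_not_scalar_num(target_Ra, "target_Ra", TRUE)
  stop_if_not_scalar_num(correlation_length, "correlation_length", TRUE)
  if (correlation_length < 2 * pixel_size)
    stop("'correlation_length' must be >= 2 * pixel_size")
  if (length(lacunae) && !all(vapply(lacunae, inherits, logical(1), "lacuna_spec")))
    stop("'lacunae' must be a list of lacuna_spec objects")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, target_Ra = target_Ra,
                 correlation_length = correlation_length,
                 tilt = as.numeric(tilt), lacunae = lacunae,
                 seed = as.integer(seed)),
            class = "surface_spec")
}

#' Specification of one elliptical lacuna
#'
#' A smooth elliptical depression: depth profile
#' \eqn{d (1 - r^2)^2} inside the ellipse of semi-axes (a, b) centred at
#' (x, y), where r is the normalized elliptical radius. Healthy-cartilage
#' lacunae are over 2 um deep; those on worn surfaces about 500 nm.
#'
#' @param center numeric length-2, centre (x, y) in nm.
#' @param semi_axes numeric length-2, semi-axes (a, b) in nm (> 0).
#' @param depth maximum depth in nm (> 0).
#' @return An object of class \code{"lacuna_spec"}.
#' @export
lacuna_spec <- function(center, semi_axes, depth) {
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("'semi_axes' must be > 0")
  stop_if_not_scalar_num(depth, "depth", TRUE)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), depth = depth),
            class = "lacuna_spec")
}

# Circular (FFT) convolution of white noise with a Gaussian kernel:
# an isotropic random field whose autocorrelation is Gaussian with 1/e
# length `corr_px` pixels (kernel sigma = corr_px / 2).
gaussian_random_field <- function(nx, ny, corr_px) {
  noise <- matrix(stats::rnorm(nx * ny), nx, ny)
  sigma <- corr_px / 2
  dx <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  dy <- pmin(0:(ny - 1), ny - (0:(ny - 1)))
  kern <- exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE))
  f / (nx * ny)
}

#' Generate a synthetic AFM height map
#'
#' Builds the surface in three steps: (1) an isotropic correlated random
#' texture (white noise smoothed to the requested correlation length by a
#' Gaussian kernel, via circular FFT convolution), rescaled so the grand
#' mean of the row-profile Ra equals \code{target_Ra} exactly;
#' (2) lacunae subtracted as smooth elliptical depressions; (3) the tilt
#' plane added last. Fixed seeds give bitwise-identical maps.
#'
#' @param spec a \code{\link{surface_spec}}.
#' @return An \code{\link{height_map}} with an \code{Ar_label} of the form
#'   \code{"<w>x<h>"} in um. A lacuna whose ellipse extends outside the grid
#'   is rejected with an error.
#' @examples
#' hm <- generate_height_map(surface_spec(64, 64, pixel_size = 35,
#'                                        target_Ra = 86, seed = 7))
#' mean(vapply(extract_profiles(hm), compute_Ra, numeric(1)))  # 86
#' @export
generate_height_map <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  ps <- spec$pixel_size
  Lx <- spec$nx * ps; Ly <- spec$ny * ps
  for (lac in spec$lacunae) {
    if (lac$center[1] - lac$semi_axes[1] < 0 ||
        lac$center[1] + lac$semi_axes[1] > Lx ||
        lac$center[2] - lac$semi_axes[2] < 0 ||
        lac$center[2] + lac$semi_axes[2] > Ly)
      stop("lacuna extends outside the scan area")
  }
  z <- with_seed(spec$seed,
                 gaussian_random_field(spec$nx, spec$ny,
                                       spec$correlation_length / ps))
  z <- z - mean(z)
  # row Ra is homogeneous of degree 1: rescale once, exactly
  ra_now <- mean(apply(z, 1, function(r) mean(abs(r - mean(r)))))
  z <- z * (spec$target_Ra / ra_now)
  if (length(spec$lacunae)) {
    xs <- (seq_len(spec$nx) - 0.5) * ps
    ys <- (seq_len(spec$ny) - 0.5) * ps
    for (lac in spec$lacunae) {
      r2 <- outer(((xs - lac$center[1]) / lac$semi_axes[1])^2,
                  ((ys - lac$center[2]) / lac$semi_axes[2])^2, "+")
      z <- z - lac$depth * ifelse(r2 < 1, (1 - r2)^2, 0)
    }
  }
  if (any(spec$tilt != 0))
    z <- z + outer(seq_len(spec$nx) * spec$tilt[1],
                   seq_len(spec$ny) * spec$tilt[2], "+")
  lab <- sprintf("%gx%g", Lx / 1000, Ly / 1000)
  height_map(z, ps, lab)
}

#' Specification of a synthetic Hertzian force curve
#'
#' Describes a force curve to simulate for a prescribed (constant or
#' depth-varying) Young's modulus, with the probe constants of the Hertz
#' model.
#'
#' @param E_profile the ground-truth modulus in MPa: a single number
#'   (constant E), a function of depth h in nm, or a data frame with
#'   columns \code{h}, \code{E} (linearly interpolated).
#' @param params a \code{\link{hertz_params}} object.
#' @param h_max maximum indentation depth, nm (> 0).
#' @param n_contact number of post-contact samples on the uniform depth
#'   grid.
#' @param n_baseline number of pre-contact baseline samples.
#' @param noise_sd additive Gaussian noise sd on the deflection, nm
#'   (>= 0); the stage position is treated as exactly commanded.
#' @param seed integer seed.
#' @return An object of class \code{"curve_spec"}.
#' @export
curve_spec <- function(E_profile, params = hertz_params(), h_max = 200,
                       n_contact = 100L, n_baseline = 50L, noise_sd = 0,
                       seed = 1L) {
  stopifnot(inherits(params, "hertz_params"))
  stop_if_not_scalar_num(h_max, "h_max", TRUE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_contact < 4L || n_baseline < 3L)
    stop("need n_contact >= 4 and n_baseline >= 3")
  structure(list(E_profile = E_profile, params = params, h_max = h_max,
                 n_contact = as.integer(n_contact),
                 n_baseline = as.integer(n_baseline),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "curve_spec")
}

# Normalize an E_profile spec to a vectorized function h [nm] -> E [MPa]
as_E_function <- function(E_profile) {
  if (is.function(E_profile)) return(E_profile)
  if (is.numeric(E_profile) && length(E_profile) == 1L) {
    E0 <- E_profile
    return(function(h) rep(E0, length(h)))
  }
  if (is.data.frame(E_profile) && all(c("h", "E") %in% names(E_profile)))
    return(function(h) stats::approx(E_profile$h, E_profile$E, xout = h,
                                     rule = 2)$y)
  stop("'E_profile' must be a number, a function of h, or a data frame (h, E)")
}

# Hertz forward model: deflection (nm) at depth h (nm) for modulus E (MPa)
hertz_deflection <- function(h, E, params) {
  E_Pa <- E * 1e6
  4 * E_Pa * sqrt(params$R * .NM) * (h * .NM)^1.5 /
    (3 * (1 - params$V^2) * params$k) / .NM
}

#' Generate a synthetic Hertzian force curve
#'
#' Forward-simulates the approach segment: on a uniform depth grid
#' \eqn{h \in (0, h_{max}]} the deflection is the Hertz inverse
#' \eqn{Zdefl = 4 E(h) \sqrt{R}\, h^{3/2} / (3 (1 - V^2) k)} and the stage
#' position \eqn{Zpos = h + Zdefl}; \code{n_baseline} zero-deflection
#' samples and the contact sample (Zpos = 0) are prepended, and Gaussian
#' noise of sd \code{noise_sd} is added to the deflection. The true contact
#' index is recorded in the returned curve for detector validation.
#'
#' @param spec a \code{\link{curve_spec}}; the modulus must be positive
#'   over the whole depth grid.
#' @return An \code{\link{force_curve}} with attribute
#'   \code{true_contact = n_baseline + 1}.
#' @examples
#' cs <- curve_spec(E_profile = 1.0, h_max = 200, noise_sd = 0)
#' fc <- generate_force_curve(cs)
#' range(compute_E_profile(fc)$E)  # 1.0 MPa throughout
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  Efun <- as_E_function(spec$E_profile)
  h <- seq(spec$h_max / spec$n_contact, spec$h_max,
           length.out = spec$n_contact)
  E <- Efun(h)
  if (any(!is.finite(E)) || any(E <= 0))
    stop("E_profile must be positive over (0, h_max]")
  zd_contact <- hertz_deflection(h, E, spec$params)
  zp_contact <- h + zd_contact
  step <- spec$h_max / spec$n_contact
  zp_base <- -(spec$n_baseline:1) * step
  Zpos <- c(zp_base, 0, zp_contact)
  Zdefl <- c(numeric(spec$n_baseline + 1L), zd_contact)
  if (spec$noise_sd > 0)
    Zdefl <- Zdefl + with_seed(spec$seed,
                               stats::rnorm(length(Zdefl), 0, spec$noise_sd))
  force_curve(Zpos, Zdefl, spec$params,
              true_contact = spec$n_baseline + 1L)
}

#' Generate a synthetic dehydration series
#'
#' Simulates specimen drying under the power law
#' \eqn{m_i = m_0 (1 + t_i)^b (1 + \epsilon_i)} with multiplicative
#' Gaussian noise \eqn{\epsilon_i \sim N(0, noise\_sd)}.
#'
#' @param m0 initial mass (> 0).
#' @param b drying exponent (< 0); default \code{\link{dehydration_b}()}.
#' @param times observation times in hours (>= 0, strictly increasing).
#' @param noise_sd relative noise sd (>= 0).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return A \code{\link{dehydration_series}}.
#' @export
generate_dehydration_series <- function(m0, b = dehydration_b(),
                                        times = 0:24, noise_sd = 0.01,
                                        seed = 1L) {
  stop_if_not_scalar_num(m0, "m0", TRUE)
  stop_if_not_scalar_num(b, "b")
  if (b >= 0) stop("'b' must be < 0 for drying")
  if (any(times < 0)) stop("'times' must be >= 0")
  m <- predict_mass(times, m0, b)
  if (noise_sd > 0)
    m <- m * (1 + with_seed(seed, stats::rnorm(length(times), 0, noise_sd)))
  if (any(m <= 0))
    stop("noise drove a simulated mass non-positive; reduce 'noise_sd'")
  dehydration_series(times, m)
}
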