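#' AFM height map
#'
#' Construct an AFM height map: a rectangular grid of surface heights (nm)
#' together with the lateral pixel size (nm/pixel) and a scan-area label.
#' Height maps are the input to leveling, roughness parameters, lacuna
#' detection and the areal parameter Sa.
#'
#' @param heights numeric matrix of heights in nm; rows are scan lines
#'   (fast-scan direction), all values finite.
#' @param pixel_size lateral sampling distance in nm/pixel (> 0).
#' @param Ar_label scan-area label; conventionally one of \code{"3x3"},
#'   \code{"9x9"}, \code{"18x18"} (um^2) or any custom string.
#' @return An object of class \code{"afm_height_map"}: the matrix with
#'   attributes \code{pixel_size} and \code{Ar_label}.
#' @examples
#' hm <- height_map(matrix(rnorm(64 * 64), 64), pixel_size = 35, Ar_label = "custom")
#' compute_Sa(level_height_map(hm))
#' @export
height_map <- function(heights, pixel_size, Ar_label = "custom") {
  heights <- as.matrix(heights)
  if (!is.numeric(heights) || any(!is.finite(heights)))
    stop("'heights' must be a numeric matrix of finite values")
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  structure(heights,
            pixel_size = as.numeric(pixel_size),
            Ar_label = as.character(Ar_label),
            class = c("afm_height_map", "matrix", "array"))
}

#' @export
print.afm_height_map <- function(x, ...) {
  ps <- attr(x, "pixel_size")
  cat(sprintf("AFM height map: %d x %d px, pixel size %.3g nm (area %s)\n",
              nrow(x), ncol(x), ps, attr(x, "Ar_label")))
  cat(sprintf("  height range: [%.3g, %.3g] nm, mean %.3g nm\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
plot.afm_height_map <- function(x, main = "AFM height map", ...) {
  ps <- attr(x, "pixel_size")
  graphics::image(x = seq_len(nrow(x)) * ps, y = seq_len(ncol(x)) * ps,
                  z = unclass(x), xlab = "x [nm]", ylab = "y [nm]",
                  main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "terrain"), ...)
  invisible(x)
}

#' Remove the least-squares plane from a height map
#'
#' AFM scans carry an instrumental tilt; roughness parameters are defined on
#' the leveled surface. A first-order (plane-only) fit is removed: the output
#' has zero mean and refitting a plane yields coefficients that vanish to
#' numerical precision. A constant map levels to the zero map. Leveling is
#' idempotent.
#'
#' @param map an \code{\link{height_map}} with at least 3x3 pixels.
#' @return A leveled \code{afm_height_map} of the same dimensions.
#' @export
level_height_map <- function(map) {
  stopifnot(inherits(map, "afm_height_map"))
  if (nrow(map) < 3L || ncol(map) < 3L)
    stop("height map must be at least 3x3 to level")
  z <- unclass(map)
  ij <- expand.grid(i = seq_len(nrow(z)), j = seq_len(ncol(z)))
  fit <- stats::lm.fit(cbind(1, ij$i, ij$j), as.vector(z))
  res <- matrix(fit$residuals, nrow(z), ncol(z))
  height_map(res, attr(map, "pixel_size"), attr(map, "Ar_label"))
}

#' Extract row profiles from a height map
#'
#' One profile per grid row (the fast-scan direction), in row order, with
#' spacing equal to the pixel size. Profiles are the unit on which Ra, Rp
#' and S are computed.
#'
#' @param map an \code{\link{height_map}}, normally leveled first.
#' @return A list of \code{\link{afm_profile}} objects, one per row.
#' @export
extract_profiles <- function(map) {
  stopifnot(inherits(map, "afm_height_map"))
  ps <- attr(map, "pixel_size")
  lapply(seq_len(nrow(map)), function(i) afm_profile(unclass(map)[i, ], ps))
}

#' AFM line profile
#'
#' A 1-D height sequence (nm) with uniform spacing (nm) — one scan line of a
#' height map, or any extracted section. Profiles are the domain of the
#' amplitude parameters Ra and Rp and the spacing parameter S.
#'
#' @param y numeric vector of heights in nm, length >= 3.
#' @param spacing sample spacing in nm (> 0).
#' @return An object of class \code{"afm_profile"}.
#' @export
afm_profile <- function(y, spacing) {
  y <- as.numeric(y)
  if (length(y) < 3L || any(!is.finite(y)))
    stop("profile must have >= 3 finite samples")
  stop_if_not_scalar_num(spacing, "spacing", positive = TRUE)
  structure(y, spacing = as.numeric(spacing), class = "afm_profile")
}

#' @export
print.afm_profile <- function(x, ...) {
  cat(sprintf("AFM profile: %d samples, spacing %.3g nm, Ra = %.3g nm\n",
              length(x), attr(x, "spacing"), compute_Ra(x)))
  invisible(x)
}

#' Read / write a height map as a plain-text matrix
#'
#' The on-disk format is whitespace-separated numbers in nm, one grid row per
#' line; metadata (pixel size, scan-area label) travel in `#`-prefixed header
#' comments so a file round-trips to an identical object.
#'
#' @param path file path.
#' @param map an \code{afm_height_map} (for writing).
#' @return \code{read_height_map} returns an \code{afm_height_map};
#'   \code{write_height_map} returns \code{path} invisibly.
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "afm_height_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_nm: %.17g", attr(map, "pixel_size")),
               sprintf("# Ar_label: %s", attr(map, "Ar_label"))), con)
  utils::write.table(unclass(map), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1])
  }
  ps <- as.numeric(get_field("pixel_size_nm", "1"))
  lab <- get_field("Ar_label", "custom")
  z <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(z) <- NULL
  height_map(z, ps, lab)
}

#' Write a height map as a single-channel floating-point TIFF
#'
#' Heights are stored as 32-bit floats in nm. Requires the \pkg{tiff}
#' package; pixel size and label are not preserved in the TIFF and must be
#' supplied again on read.
#'
#' @inheritParams write_height_map
#' @export
write_height_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "afm_height_map"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  tiff::writeTIFF(unclass(map), path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
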