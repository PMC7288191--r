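#' Read and write force curves as CSV
#'
#' Curves are stored as headered CSV with columns \code{zpos_nm},
#' \code{zdefl_nm}; the probe constants travel in `#`-prefixed header
#' comments (\code{V}, \code{k_N_per_m}, \code{R_nm}) so a file
#' round-trips to an equivalent object.
#'
#' @param curve an \code{\link{force_curve}}.
#' @param path file path.
#' @return \code{read_force_curve} returns an \code{afm_force_curve};
#'   \code{write_force_curve} returns \code{path} invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "afm_force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- curve$params
  writeLines(c(sprintf("# V: %.17g", p$V),
               sprintf("# k_N_per_m: %.17g", p$k),
               sprintf("# R_nm: %.17g", p$R)), con)
  utils::write.csv(data.frame(zpos_nm = curve$Zpos, zdefl_nm = curve$Zdefl),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  val <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(hit)) default
    else as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  force_curve(df$zpos_nm, df$zdefl_nm,
              hertz_params(V = val("V", 0.5), k = val("k_N_per_m", 0.08),
                           R = val("R_nm", 30)))
}

#' Read and write dehydration series as CSV
#'
#' Columns \code{t_h} (hours) and \code{m} (mass).
#'
#' @param series a \code{\link{dehydration_series}}.
#' @param path file path.
#' @export
write_dehydration_series <- function(series, path) {
  stopifnot(inherits(series, "dehydration_series"))
  utils::write.csv(data.frame(t_h = series$t, m = series$m), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_dehydration_series
#' @export
read_dehydration_series <- function(path) {
  df <- utils::read.csv(path)
  dehydration_series(df$t_h, df$m)
}

#' Write the tables of a study report
#'
#' Writes the report's tables as CSV files with fixed column order and
#' 4-significant-digit floats (roughness records and summaries, percent
#' changes, wear stages, modulus summaries — whichever the report holds),
#' plus a \code{modulus_summary.json} when \pkg{jsonlite} is available.
#'
#' @param report a \code{"study_report"}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 4)
    df
  }
  emit <- function(x, name)
    if (!is.null(x)) utils::write.csv(fmt(as.data.frame(x)),
                                      file.path(dir, name), row.names = FALSE)
  emit(report$records, "roughness_records.csv")
  emit(report$summary_healthy, "roughness_summary_healthy.csv")
  emit(report$summary_worn, "roughness_summary_worn.csv")
  emit(report$percent_change, "percent_change.csv")
  emit(report$stages, "wear_stages.csv")
  emit(report$modulus, "modulus_summary.csv")
  if (!is.null(report$modulus) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(fmt(report$modulus),
                         file.path(dir, "modulus_summary.json"),
                         digits = NA)
  invisible(dir)
}
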