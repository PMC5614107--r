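# Plain-text sidecar formats: tilt-angle lists (.tlt), per-tilt defocus
# tables, TSV curves and flat key=value config files.

#' Read a tilt-angle list (.tlt)
#'
#' One angle in degrees per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the .tlt file.
#' @return Numeric vector of tilt angles in degrees.
#' @export
read_tlt <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- suppressWarnings(as.numeric(lines))
  if (any(is.na(out))) stop("malformed .tlt file: ", path, call. = FALSE)
  out
}

#' Write a tilt-angle list (.tlt)
#'
#' @param angles Numeric vector of tilt angles in degrees.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tlt <- function(angles, path) {
  writeLines(formatC(angles, format = "f", digits = 2), path)
  invisible(path)
}

#' Read a per-tilt defocus table
#'
#' Whitespace-separated, one row per tilt:
#' `index tilt_deg defocus1_nm defocus2_nm astig_angle_deg`, rows sorted by
#' index; lines beginning with `#` are comments. `defocus1` is the defocus
#' along the astigmatism axis; with astigmatism off, `defocus2 == defocus1`
#' and the angle is 0.
#'
#' @param path Path to the table.
#' @return Data frame with the five columns above plus derived `defocus`
#'   (mean, nm), `defocus_delta` (semi-difference, >= 0) and `astig_angle`
#'   (normalised so the delta is non-negative).
#' @export
read_defocus_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("index", "tilt_deg", "defocus1_nm",
                                         "defocus2_nm", "astig_angle_deg"))
  tab <- tab[order(tab$index), , drop = FALSE]
  tab$defocus <- (tab$defocus1_nm + tab$defocus2_nm) / 2
  delta <- (tab$defocus1_nm - tab$defocus2_nm) / 2
  tab$defocus_delta <- abs(delta)
  tab$astig_angle <- ifelse(delta >= 0, tab$astig_angle_deg,
                            tab$astig_angle_deg + 90)
  tab
}

#' Write a per-tilt defocus table
#'
#' @param tab Data frame with columns `index`, `tilt_deg`, `defocus1_nm`,
#'   `defocus2_nm`, `astig_angle_deg` (missing astigmatism columns default
#'   to `defocus2 = defocus1`, angle 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_defocus_table <- function(tab, path) {
  if (is.null(tab$defocus2_nm)) tab$defocus2_nm <- tab$defocus1_nm
  if (is.null(tab$astig_angle_deg)) tab$astig_angle_deg <- 0
  lines <- c("# index tilt_deg defocus1_nm defocus2_nm astig_angle_deg",
             sprintf("%d %.2f %.2f %.2f %.2f", as.integer(tab$index),
                     tab$tilt_deg, tab$defocus1_nm, tab$defocus2_nm,
                     tab$astig_angle_deg))
  writeLines(lines, path)
  invisible(path)
}

#' Write a curve (attenuation or FSC) as TSV
#'
#' @param curve Data frame (`attenuation_curve` written as
#'   `freq_invA ratio`; `fsc_curve` as `freq_invA fsc n_voxels`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  if (inherits(curve, "fsc_curve")) {
    out <- data.frame(freq_invA = curve$freq, fsc = curve$fsc,
                      n_voxels = curve$n_voxels)
  } else {
    out <- data.frame(freq_invA = curve$freq, ratio = curve$ratio)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' INI-style: `key = value` lines, `#` comments, no sections. Values are
#' returned as strings; numeric conversion is the caller's business.
#'
#' @param path Path to the config file.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  stats::setNames(trimws(vapply(kv, `[`, character(1), 3L)),
                  trimws(vapply(kv, `[`, character(1), 2L)))
}
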