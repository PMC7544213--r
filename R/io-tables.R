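# Readers/writers for the plain-text table formats used throughout the
# package: peak lists, RDC tables, relaxation tables and ITC isotherms.
# All are header-first TSV/CSV with '#' comment lines; numbering in files
# is authoritative (no renumbering on input).

split_table_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) < 1L) {
    abort(sprintf("'%s' contains no data lines", path))
  }
  sep <- if (grepl("\t", raw[keep[1]])) "\t" else ","
  list(lines = raw[keep], lineno = keep, sep = sep)
}

parse_numeric_col <- function(x, col, lineno, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-numeric value '%s' in column '%s' at line %d of '%s'",
      x[bad[1]], col, lineno[bad[1]], path
    ))
  }
  out
}

read_delim_table <- function(path, required_cols) {
  tl <- split_table_lines(path)
  fields <- strsplit(tl$lines, tl$sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  missing <- setdiff(required_cols, header)
  if (length(missing) > 0L) {
    abort(sprintf(
      "'%s' is missing required column(s): %s (found: %s)",
      path, paste(missing, collapse = ", "), paste(header, collapse = ", ")
    ))
  }
  body <- fields[-1]
  lineno <- tl$lineno[-1]
  if (length(body) == 0L) {
    abort(sprintf("'%s' has a header but no data rows", path))
  }
  nc <- length(header)
  mat <- vapply(body, function(f) {
    f <- trimws(f)
    length(f) <- nc
    f
  }, character(nc))
  mat <- matrix(mat, nrow = nc)
  out <- as_tibble(setNames(as.data.frame(t(mat), stringsAsFactors = FALSE), header))
  attr(out, "lineno") <- lineno
  out
}

#' Read an amide peak list
#'
#' Parses a tab- or comma-separated peak list with a mandatory header row
#' naming the columns `residue_number`, `residue_name`, `dH_ppm`, `dN_ppm`,
#' `intensity`. Blank lines and lines starting with `#` are skipped.
#'
#' Amide shifts are sanity-checked (1H within 0-14 ppm, 15N within
#' 90-140 ppm) with a warning, not an error, outside those windows.
#'
#' @param path Path to the peak-list file.
#' @param label Optional free-text label for the titration point
#'   (e.g. `"1:3"`); stored as the `label` attribute.
#' @return A tibble with columns `residue_number` (integer),
#'   `residue_name`, `dH_ppm`, `dN_ppm`, `intensity`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("residue_number\tresidue_name\tdH_ppm\tdN_ppm\tintensity",
#'              "2\tALA\t8.10\t121.5\t1000"), f)
#' read_peaklist(f)
read_peaklist <- function(path, label = NULL) {
  cols <- c("residue_number", "residue_name", "dH_ppm", "dN_ppm", "intensity")
  tab <- read_delim_table(path, cols)
  lineno <- attr(tab, "lineno")
  pk <- tibble(
    residue_number = as.integer(parse_numeric_col(tab$residue_number, "residue_number", lineno, path)),
    residue_name   = trimws(tab$residue_name),
    dH_ppm         = parse_numeric_col(tab$dH_ppm, "dH_ppm", lineno, path),
    dN_ppm         = parse_numeric_col(tab$dN_ppm, "dN_ppm", lineno, path),
    intensity      = parse_numeric_col(tab$intensity, "intensity", lineno, path)
  )
  validate_peaklist(pk, path)
  attr(pk, "label") <- label
  pk
}

validate_peaklist <- function(pk, context = "peak list") {
  dup <- pk$residue_number[duplicated(pk$residue_number)]
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate residue_number %s in %s",
      paste(unique(dup), collapse = ", "), context
    ))
  }
  if (any(pk$dH_ppm < 0 | pk$dH_ppm > 14, na.rm = TRUE)) {
    warn(sprintf("%s: 1H shifts outside 0-14 ppm", context))
  }
  if (any(pk$dN_ppm < 90 | pk$dN_ppm > 140, na.rm = TRUE)) {
    warn(sprintf("%s: 15N shifts outside 90-140 ppm", context))
  }
  if (any(pk$intensity < 0, na.rm = TRUE)) {
    warn(sprintf("%s: negative intensities", context))
  }
  invisible(pk)
}

#' Write a peak list to TSV
#'
#' @param peaks Peak-list tibble as returned by [read_peaklist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  hdr <- "residue_number\tresidue_name\tdH_ppm\tdN_ppm\tintensity"
  rows <- sprintf(
    "%d\t%s\t%.4f\t%.4f\t%.6g",
    peaks$residue_number, peaks$residue_name,
    peaks$dH_ppm, peaks$dN_ppm, peaks$intensity
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an RDC table
#'
#' TSV with required columns `residue_number`, `D_obs_Hz` and optional
#' `D_err_Hz` and `domain`.
#'
#' @param path Path to the RDC table.
#' @return Tibble with columns `residue_number`, `D_obs_Hz`, `D_err_Hz`
#'   (NA when absent), `domain` (NA when absent).
#' @export
read_rdc_table <- function(path) {
  tab <- read_delim_table(path, c("residue_number", "D_obs_Hz"))
  lineno <- attr(tab, "lineno")
  out <- tibble(
    residue_number = as.integer(parse_numeric_col(tab$residue_number, "residue_number", lineno, path)),
    D_obs_Hz = parse_numeric_col(tab$D_obs_Hz, "D_obs_Hz", lineno, path),
    D_err_Hz = if ("D_err_Hz" %in% names(tab)) {
      parse_numeric_col(tab$D_err_Hz, "D_err_Hz", lineno, path)
    } else NA_real_,
    domain = if ("domain" %in% names(tab)) trimws(tab$domain) else NA_character_
  )
  dup <- out$residue_number[duplicated(out$residue_number)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate residue_number %s in '%s'",
                  paste(unique(dup), collapse = ", "), path))
  }
  if (any(abs(out$D_obs_Hz) >= 60, na.rm = TRUE)) {
    warn(sprintf("'%s': |D_obs| >= 60 Hz looks implausible for 1D(NH)", path))
  }
  out
}

#' Write an RDC table to TSV
#'
#' @param rdcs Tibble with `residue_number`, `D_obs_Hz` and optionally
#'   `D_err_Hz`, `domain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(rdcs, path) {
  has_err <- "D_err_Hz" %in% names(rdcs) && any(!is.na(rdcs$D_err_Hz))
  has_dom <- "domain" %in% names(rdcs) && any(!is.na(rdcs$domain))
  hdr <- paste(c("residue_number", "D_obs_Hz",
                 if (has_err) "D_err_Hz", if (has_dom) "domain"),
               collapse = "\t")
  rows <- sprintf("%d\t%.4f", rdcs$residue_number, rdcs$D_obs_Hz)
  if (has_err) rows <- paste(rows, sprintf("%.4f", rdcs$D_err_Hz), sep = "\t")
  if (has_dom) rows <- paste(rows, rdcs$domain, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a per-residue relaxation table or a decay series
#'
#' Rate mode requires columns `residue_number`, `R1_s`, `R2_s`, `hetNOE`;
#' decay mode requires `residue_number`, `delay_ms`, `intensity`. The mode
#' is detected from the header.
#'
#' @param path Path to the TSV file.
#' @return A tibble in rate or decay layout; the layout is recorded in the
#'   `relaxation_mode` attribute (`"rates"` or `"decays"`).
#' @export
read_relaxation_table <- function(path) {
  tl <- split_table_lines(path)
  header <- trimws(strsplit(tl$lines[1], tl$sep, fixed = TRUE)[[1]])
  if (all(c("R1_s", "R2_s", "hetNOE") %in% header)) {
    tab <- read_delim_table(path, c("residue_number", "R1_s", "R2_s", "hetNOE"))
    lineno <- attr(tab, "lineno")
    out <- tibble(
      residue_number = as.integer(parse_numeric_col(tab$residue_number, "residue_number", lineno, path)),
      R1_s   = parse_numeric_col(tab$R1_s, "R1_s", lineno, path),
      R2_s   = parse_numeric_col(tab$R2_s, "R2_s", lineno, path),
      hetNOE = parse_numeric_col(tab$hetNOE, "hetNOE", lineno, path)
    )
    if (any(out$R1_s <= 0 | out$R2_s <= 0)) {
      abort(sprintf("'%s': R1 and R2 must be positive", path))
    }
    if (any(out$hetNOE > 1.2, na.rm = TRUE)) {
      warn(sprintf("'%s': hetNOE above the theoretical maximum 1.2", path))
    }
    attr(out, "relaxation_mode") <- "rates"
  } else if (all(c("delay_ms", "intensity") %in% header)) {
    tab <- read_delim_table(path, c("residue_number", "delay_ms", "intensity"))
    lineno <- attr(tab, "lineno")
    out <- tibble(
      residue_number = as.integer(parse_numeric_col(tab$residue_number, "residue_number", lineno, path)),
      delay_ms  = parse_numeric_col(tab$delay_ms, "delay_ms", lineno, path),
      intensity = parse_numeric_col(tab$intensity, "intensity", lineno, path)
    )
    attr(out, "relaxation_mode") <- "decays"
  } else {
    abort(sprintf(
      "'%s': header must name either R1_s/R2_s/hetNOE or delay_ms/intensity", path
    ))
  }
  out
}

#' Write a relaxation table to TSV
#'
#' @param relax Relaxation tibble in rate or decay layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relaxation_table <- function(relax, path) {
  if (all(c("R1_s", "R2_s", "hetNOE") %in% names(relax))) {
    hdr <- "residue_number\tR1_s\tR2_s\thetNOE"
    rows <- sprintf("%d\t%.5f\t%.5f\t%.5f",
                    relax$residue_number, relax$R1_s, relax$R2_s, relax$hetNOE)
  } else {
    hdr <- "residue_number\tdelay_ms\tintensity"
    rows <- sprintf("%d\t%.3f\t%.6g",
                    relax$residue_number, relax$delay_ms, relax$intensity)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ITC isotherm
#'
#' CSV with metadata header lines `# cell_volume_mL=`, `# syringe_conc_uM=`,
#' `# cell_conc_uM=`, `# temperature_C=` followed by a header row and rows
#' `injection_index, volume_uL, heat_ucal, use_flag`.
#'
#' @param path Path to the isotherm CSV.
#' @return An `itc_isotherm` tibble (columns `injection`, `volume_uL`,
#'   `heat_ucal`, `use_flag`, derived `titrant_uM`, `titrand_uM`,
#'   `molar_ratio`) whose attributes carry the cell volume, concentrations
#'   and temperature.
#' @export
read_isotherm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  meta_val <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), raw, value = TRUE)
    if (length(ln) < 1L) abort(sprintf("'%s': missing '# %s=' header", path, key))
    as.numeric(sub(paste0("^#\\s*", key, "="), "", ln[1]))
  }
  v0   <- meta_val("cell_volume_mL")
  syr  <- meta_val("syringe_conc_uM")
  cell <- meta_val("cell_conc_uM")
  temp <- meta_val("temperature_C")
  tab <- read_delim_table(path, c("injection_index", "volume_uL", "heat_ucal", "use_flag"))
  lineno <- attr(tab, "lineno")
  inj <- tibble(
    injection = as.integer(parse_numeric_col(tab$injection_index, "injection_index", lineno, path)),
    volume_uL = parse_numeric_col(tab$volume_uL, "volume_uL", lineno, path),
    heat_ucal = parse_numeric_col(tab$heat_ucal, "heat_ucal", lineno, path),
    use_flag  = as.integer(parse_numeric_col(tab$use_flag, "use_flag", lineno, path))
  )
  new_isotherm(inj, cell_volume_mL = v0, syringe_conc_uM = syr,
               cell_conc_uM = cell, temperature_C = temp)
}

#' Write an ITC isotherm to CSV
#'
#' @param isotherm An `itc_isotherm` as returned by [read_isotherm()] or
#'   [gen_isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(isotherm, path) {
  sch <- isotherm_schedule(isotherm)
  hdr <- c(
    sprintf("# cell_volume_mL=%.6g", sch$cell_volume_mL),
    sprintf("# syringe_conc_uM=%.6g", sch$syringe_conc_uM),
    sprintf("# cell_conc_uM=%.6g", sch$cell_conc_uM),
    sprintf("# temperature_C=%.6g", sch$temperature_C),
    "injection_index,volume_uL,heat_ucal,use_flag"
  )
  rows <- sprintf("%d,%.3f,%.6f,%d",
                  isotherm$injection, isotherm$volume_uL,
                  isotherm$heat_ucal, isotherm$use_flag)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
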