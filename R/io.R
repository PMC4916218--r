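# Schema-validated CSV readers/writers for the four pipeline inputs.
#
# Schemas (one-line header, comma separated):
#   peaks.csv     injection_id, run_order, role, compound, rt_min, area,
#                 delta_raw_permil, delta_sem_permil, h3_factor
#   samples.csv   injection_id, strain, donor, sulfate_mM, bio_rep,
#                 water_delta_permil
#   standards.csv standard_name, compound, known_delta_permil,
#                 n_methyl_H_added
#   od.csv        strain, donor, sulfate_mM, bio_rep, time_h, od600
#
# Roles: sample | fame_mix_standard | alkane_ladder. Run order (not wall
# clock) is the bracketing axis.

PEAKS_COLUMNS <- c("injection_id", "run_order", "role", "compound", "rt_min",
                   "area", "delta_raw_permil", "delta_sem_permil", "h3_factor")
SAMPLES_COLUMNS <- c("injection_id", "strain", "donor", "sulfate_mM",
                     "bio_rep", "water_delta_permil")
STANDARDS_COLUMNS <- c("standard_name", "compound", "known_delta_permil",
                       "n_methyl_H_added")
OD_COLUMNS <- c("strain", "donor", "sulfate_mM", "bio_rep", "time_h", "od600")

INJECTION_ROLES <- c("sample", "fame_mix_standard", "alkane_ladder")
STRAINS <- c("wild-type", "nfnA-2", "nfnB-2")
DONORS <- c("pyruvate", "malate", "fumarate", "lactate")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# coerce a character column to numeric, reporting 1-based data-row numbers
# of values that fail to parse (blank cells are allowed NA)
numeric_column <- function(x, column, what, errors) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(out))
  na_marked <- which(raw == "NA")
  for (i in c(bad, na_marked)) {
    errors$add(sprintf("row %d: non-numeric %s value '%s'", i, column, raw[i]))
  }
  out
}

row_error_collector <- function() {
  msgs <- character(0)
  list(add = function(msg) msgs <<- c(msgs, msg),
       get = function() msgs)
}

#' Read a per-injection peak table
#'
#' Parses `peaks.csv` (schema in the package vignette), validates the
#' header and row values, and returns the injections in run order. Rows
#' with non-numeric `area` or delta values are dropped and reported in the
#' `row_errors` attribute (with their line numbers) rather than aborting
#' the run.
#'
#' @param path path to a peaks CSV file, or a data.frame already in that
#'   schema.
#' @return a `peak_table`: data.frame of peaks ordered by `run_order`, with
#'   attribute `row_errors` (character vector, possibly empty) and
#'   attribute `injections` accessible via [injections()].
#' @export
read_peak_table <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop(sprintf("peaks file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  check_columns(df, PEAKS_COLUMNS, "peaks table")
  errors <- row_error_collector()
  df$run_order <- numeric_column(df$run_order, "run_order", "peaks", errors)
  df$rt_min <- numeric_column(df$rt_min, "rt_min", "peaks", errors)
  df$area <- numeric_column(df$area, "area", "peaks", errors)
  df$delta_raw_permil <- numeric_column(df$delta_raw_permil,
                                        "delta_raw_permil", "peaks", errors)
  df$delta_sem_permil <- numeric_column(df$delta_sem_permil,
                                        "delta_sem_permil", "peaks", errors)
  df$h3_factor <- numeric_column(df$h3_factor, "h3_factor", "peaks", errors)
  bad_role <- which(!df$role %in% INJECTION_ROLES)
  for (i in bad_role) {
    errors$add(sprintf("row %d: unknown role '%s'", i, df$role[i]))
  }
  msgs <- errors$get()
  # a row is dropped only if one of its load-bearing fields failed to parse
  drop <- is.na(df$run_order) | !df$role %in% INJECTION_ROLES |
    (is.na(df$area) & is.na(df$delta_raw_permil))
  kept <- df[!drop, , drop = FALSE]
  if (any(kept$rt_min <= 0, na.rm = TRUE)) {
    stop("peaks table: retention times must be positive")
  }
  if (any(kept$area < 0, na.rm = TRUE)) {
    stop("peaks table: peak areas must be non-negative")
  }
  kept <- kept[order(kept$run_order), , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, row_errors = msgs, class = c("peak_table", "data.frame"))
}

#' Write a peak table
#'
#' Inverse of [read_peak_table()]; values round-trip bit-exactly for
#' text-representable numbers (written with 15 significant digits).
#'
#' @param peaks a `peak_table` or data.frame in the peaks schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  check_columns(peaks, PEAKS_COLUMNS, "peaks table")
  write_csv15(as.data.frame(peaks)[PEAKS_COLUMNS], path)
}

# full-precision CSV writer shared by all outputs
write_csv15 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 15, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split a peak table into injections
#'
#' @param peaks a `peak_table`.
#' @return a list of `injection` objects (injection_id, run_order, role,
#'   h3_factor, peaks data.frame), ordered by run order.
#' @export
injections <- function(peaks) {
  ids <- unique(peaks$injection_id[order(peaks$run_order)])
  out <- lapply(ids, function(id) {
    p <- peaks[peaks$injection_id == id, , drop = FALSE]
    ro <- unique(p$run_order)
    if (length(ro) != 1) {
      stop(sprintf("injection %s: inconsistent run_order", id))
    }
    structure(
      list(injection_id = id, run_order = ro, role = p$role[1],
           h3_factor = p$h3_factor[1],
           peaks = p[, c("compound", "rt_min", "area", "delta_raw_permil",
                         "delta_sem_permil")]),
      class = "injection"
    )
  })
  ro <- vapply(out, `[[`, numeric(1), "run_order")
  if (anyDuplicated(ro)) stop("injections: run_order values must be unique")
  out
}

#' @export
print.injection <- function(x, ...) {
  cat(sprintf("<injection %s> run %g, role %s, %d peak(s)\n",
              x$injection_id, x$run_order, x$role, nrow(x$peaks)))
  invisible(x)
}

#' Read the sample sheet
#'
#' @param path path to `samples.csv` or an equivalent data.frame.
#' @return validated data.frame linking sample injections to strain,
#'   electron donor, sulfate concentration, biological replicate, and the
#'   medium-water delta-2H.
#' @export
read_samples <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop(sprintf("samples file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  check_columns(df, SAMPLES_COLUMNS, "samples table")
  if (!all(df$strain %in% STRAINS)) {
    stop(sprintf("samples table: unknown strain(s): %s",
                 paste(unique(setdiff(df$strain, STRAINS)), collapse = ", ")))
  }
  if (!all(df$donor %in% DONORS)) {
    stop(sprintf("samples table: unknown donor(s): %s",
                 paste(unique(setdiff(df$donor, DONORS)), collapse = ", ")))
  }
  if (any(df$sulfate_mM < 0)) stop("samples table: sulfate_mM must be >= 0")
  df
}

#' Read the standards table
#'
#' Rows carry the known compositions used by the reduction: the coinjected
#' reference (`standard_name = "coinjected_C24"`, known delta of the methyl
#' ester vs V-SMOW), the derivatized isotope standards
#' (`"myristic_acid"`, `"phthalic_acid"`: known free-acid delta and methyl
#' hydrogens added), and the bracketing mix (`"fame_mix"`, one row per mix
#' compound).
#'
#' @param path path to `standards.csv` or an equivalent data.frame.
#' @return validated data.frame.
#' @export
read_standards <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop(sprintf("standards file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  check_columns(df, STANDARDS_COLUMNS, "standards table")
  if (any(df$known_delta_permil <= -1000)) {
    stop("standards table: known deltas must exceed -1000 permil")
  }
  df
}

#' Read OD600 growth time series
#'
#' @param path path to `od.csv` or an equivalent data.frame.
#' @return validated data.frame, ordered by condition and time.
#' @export
read_od <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop(sprintf("od file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  check_columns(df, OD_COLUMNS, "od table")
  if (any(df$od600 < 0)) stop("od table: od600 must be >= 0")
  df[order(df$strain, df$donor, df$sulfate_mM, df$bio_rep, df$time_h), ,
     drop = FALSE]
}

# canonical cell key used across outputs
cell_key <- function(strain, donor, sulfate_mM) {
  paste(strain, donor, ifelse(sulfate_mM > 0, "sulfate", "fermentation"),
        sep = "|")
}
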