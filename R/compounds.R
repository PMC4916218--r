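# Fatty-acid nomenclature and hydrogen accounting.
#
# A saturated mono-carboxylic fatty acid with n carbons has formula
# C_n H_{2n} O_2; each double bond removes two hydrogens. On methylation
# (FAME derivatization) the exchangeable carboxyl O-H is lost and three
# methanol-derived hydrogens are gained. Branching rearranges carbons but
# never changes hydrogen counts.

#' Parse a fatty-acid label
#'
#' Accepts labels of the form `"<prefix>C<k>:<d>"` with optional branching
#' prefix `n-`/`i-`/`a-` (or the long forms `iso-`/`anteiso-`) and an
#' optional double-bond position suffix `" D9"` / `" Δ9"`. A missing
#' prefix means a straight (normal) chain. Reparsing a canonical label is
#' idempotent.
#'
#' @param label character vector of fatty-acid labels, e.g. `"a-C17:0"`,
#'   `"n-C16:1 Δ9"`.
#' @return for a single label, a `fatty_acid` object (list with `n_carbon`,
#'   `branching`, `n_double_bonds`, `db_position`, `label`); for a vector,
#'   a list of such objects.
#' @examples
#' parse_lipid_label("a-C17:0")
#' @export
parse_lipid_label <- function(label) {
  if (length(label) > 1) return(lapply(label, parse_lipid_label))
  stopifnot(is.character(label), length(label) == 1)
  raw <- trimws(label)
  pat <- "^(n-|i-|a-|iso-|anteiso-)?C([0-9]+):([0-9]+)(\\s*(Δ|D)([0-9]+))?$"
  m <- regmatches(raw, regexec(pat, raw))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse fatty-acid label '%s'", raw))
  }
  branching <- switch(ifelse(m[2] == "", "n-", m[2]),
                      "n-" = "normal",
                      "i-" = "iso", "iso-" = "iso",
                      "a-" = "anteiso", "anteiso-" = "anteiso")
  n_carbon <- as.integer(m[3])
  n_db <- as.integer(m[4])
  db_position <- if (m[7] != "") as.integer(m[7]) else NA_integer_
  fatty_acid(n_carbon, branching, n_db, db_position)
}

#' Construct a fatty-acid identity
#'
#' @param n_carbon total carbon number (>= 4).
#' @param branching `"normal"`, `"iso"` or `"anteiso"`.
#' @param n_double_bonds number of C=C double bonds (>= 0, at most
#'   `floor((n_carbon - 2) / 2)`).
#' @param db_position optional delta position of the double bond
#'   (`NA` when unidentified).
#' @return object of class `fatty_acid`; its `label` field is the
#'   canonical text form.
#' @export
fatty_acid <- function(n_carbon, branching = "normal", n_double_bonds = 0L,
                       db_position = NA_integer_) {
  n_carbon <- as.integer(n_carbon)
  n_double_bonds <- as.integer(n_double_bonds)
  branching <- match.arg(branching, c("normal", "iso", "anteiso"))
  if (n_carbon < 4) stop("fatty_acid: n_carbon must be >= 4")
  if (n_double_bonds < 0 || n_double_bonds > floor((n_carbon - 2) / 2)) {
    stop(sprintf("fatty_acid: impossible unsaturation C%d:%d",
                 n_carbon, n_double_bonds))
  }
  prefix <- c(normal = "n-", iso = "i-", anteiso = "a-")[[branching]]
  label <- sprintf("%sC%d:%d", prefix, n_carbon, n_double_bonds)
  if (!is.na(db_position)) label <- sprintf("%s Δ%d", label, db_position)
  structure(
    list(n_carbon = n_carbon, branching = branching,
         n_double_bonds = n_double_bonds,
         db_position = as.integer(db_position), label = label),
    class = "fatty_acid"
  )
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s (%d C, %s, %d double bond%s)\n",
              x$label, x$n_carbon, x$branching, x$n_double_bonds,
              if (x$n_double_bonds == 1) "" else "s"))
  invisible(x)
}

#' Hydrogen inventory of a fatty acid and its methyl ester
#'
#' Counts total and non-exchangeable hydrogen in the free acid
#' (`C_n H_{2n - 2d} O_2`; the single carboxyl O-H is the only
#' exchangeable hydrogen) and in the methyl ester (three methanol-derived
#' hydrogens added, carboxyl hydrogen lost). Also records the hydrogen
#' contributed by the chain-extension primer: 3 (acetyl) for straight
#' chains, 7 (isobutyryl, valine-derived) for even-carbon iso acids, and
#' 9 (isovaleryl / 2-methylbutyryl, leucine- / isoleucine-derived) for
#' odd-carbon iso and anteiso acids.
#'
#' @param fa a `fatty_acid` (or a label parseable by
#'   [parse_lipid_label()]).
#' @return object of class `hydrogen_inventory`: list with `h_total_acid`,
#'   `h_nonexch_acid`, `h_methyl_added`, `h_fame`, `h_primer`,
#'   `n_carboxyl`, `label`.
#' @examples
#' hydrogen_inventory("a-C17:0")  # 34 total, 33 non-exchangeable, 36 FAME
#' @export
hydrogen_inventory <- function(fa) {
  if (is.character(fa)) fa <- parse_lipid_label(fa)
  stopifnot(inherits(fa, "fatty_acid"))
  h_total <- 2L * fa$n_carbon - 2L * fa$n_double_bonds
  h_primer <- switch(fa$branching,
    normal  = 3L,
    iso     = if (fa$n_carbon %% 2 == 0) 7L else 9L,
    anteiso = 9L
  )
  # primer accounting presumes the intact primer hydrogens survive in the
  # chain; for acids too small/unsaturated to retain them it is undefined
  if (h_primer > h_total - 1L) h_primer <- NA_integer_
  new_hydrogen_inventory(h_total, n_carboxyl = 1L, h_primer = h_primer,
                         label = fa$label)
}

#' Hydrogen inventory of a (poly)carboxylic acid from its formula
#'
#' For derivatization standards that are not simple fatty acids (e.g.
#' phthalic acid, a diacid), counts follow directly from the molecular
#' formula: every carboxyl O-H is exchangeable and each acid group gains
#' three methyl hydrogens on esterification.
#'
#' @param n_carbon carbon number (metadata only).
#' @param n_H_total total hydrogen count of the free acid.
#' @param n_carboxyl number of carboxylic acid groups (>= 1).
#' @param label optional compound label.
#' @return a `hydrogen_inventory`.
#' @examples
#' polyacid_inventory(8, 6, 2, "phthalic acid")  # C8H6O4 -> 4 + 6 = 10 FAME H
#' @export
polyacid_inventory <- function(n_carbon, n_H_total, n_carboxyl,
                               label = NA_character_) {
  n_H_total <- as.integer(n_H_total)
  n_carboxyl <- as.integer(n_carboxyl)
  if (n_carboxyl < 1) stop("polyacid_inventory: n_carboxyl must be >= 1")
  if (n_H_total < n_carboxyl) {
    stop("polyacid_inventory: fewer hydrogens than carboxyl groups")
  }
  new_hydrogen_inventory(n_H_total, n_carboxyl = n_carboxyl,
                         h_primer = NA_integer_, label = label)
}

new_hydrogen_inventory <- function(h_total, n_carboxyl, h_primer, label) {
  h_nonexch <- h_total - n_carboxyl
  h_methyl <- 3L * n_carboxyl
  structure(
    list(h_total_acid = as.integer(h_total),
         h_nonexch_acid = as.integer(h_nonexch),
         h_methyl_added = as.integer(h_methyl),
         h_fame = as.integer(h_nonexch + h_methyl),
         h_primer = as.integer(h_primer),
         n_carboxyl = as.integer(n_carboxyl),
         label = label),
    class = "hydrogen_inventory"
  )
}

#' @export
print.hydrogen_inventory <- function(x, ...) {
  cat(sprintf("<hydrogen_inventory> %s\n", x$label))
  cat(sprintf("  free acid: %d H total, %d non-exchangeable\n",
              x$h_total_acid, x$h_nonexch_acid))
  cat(sprintf("  methyl ester: %d H (+%d methyl)\n",
              x$h_fame, x$h_methyl_added))
  if (!is.na(x$h_primer)) cat(sprintf("  primer H: %d\n", x$h_primer))
  invisible(x)
}

#' The packaged compound library
#'
#' Reads `compounds.csv` shipped with the package: every fatty acid used by
#' the analysis plus the derivatization and coinjection standards, with
#' derived hydrogen inventories.
#'
#' @return data.frame with columns `compound`, `class`, `n_carbon`,
#'   `branching`, `n_double_bonds`, `n_carboxyl`, `h_total_acid`,
#'   `h_nonexch_acid`, `h_methyl_added`, `h_fame`, `h_primer`.
#' @export
compound_library <- function() {
  path <- system.file("extdata", "compounds.csv", package = "lipid2h",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# inventory lookup for a vector of compound labels, using the grammar for
# fatty acids and the library for everything else; returns a data.frame
inventory_table <- function(labels) {
  lib <- compound_library()
  out <- lapply(labels, function(lb) {
    i <- match(lb, lib$compound)
    if (!is.na(i)) {
      lib[i, c("h_total_acid", "h_nonexch_acid", "h_methyl_added",
               "h_fame", "h_primer")]
    } else {
      inv <- hydrogen_inventory(lb)
      data.frame(h_total_acid = inv$h_total_acid,
                 h_nonexch_acid = inv$h_nonexch_acid,
                 h_methyl_added = inv$h_methyl_added,
                 h_fame = inv$h_fame, h_primer = inv$h_primer)
    }
  })
  cbind(data.frame(compound = labels, stringsAsFactors = FALSE),
        do.call(rbind, out))
}
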