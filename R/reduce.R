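# End-to-end reduction of one measurement campaign: QC, referencing,
# methyl calibration and correction, pseudoreplicate aggregation, profile
# quantitation, and pool fractionation, per strain x condition cell.

#' Reduce a study's raw peak tables to fractionations
#'
#' Runs the full isotope data reduction: (1) bracketing-standard QC with
#' the stated discard rule; (2) re-referencing of sample and
#' derivatization-standard peaks from the coinjected reference to V-SMOW;
#' (3) methyl-hydrogen calibration from the derivatized standards and mass
#' balance correction of every sample FAME; (4) pseudoreplicate
#' aggregation within biological replicates, then across them, with the
#' session RMS as an instrument uncertainty floor; (5) relative-abundance
#' quantitation against the coinjected internal standard; (6) per-lipid
#' fractionation against the medium water and the pool-weighted total.
#'
#' Derivatization standards (known free-acid composition, rows of the
#' standards table with `n_methyl_H_added > 0`) are located in the
#' injection sequence by their compound labels; they are sample-role
#' injections with no entry in the sample sheet. The bracketing discard
#' rule applies to biological samples; calibration standards are
#' aggregated across the whole session.
#'
#' @param peaks,samples,standards paths to the respective CSV files (or
#'   data.frames in the documented schemas).
#' @param qc_threshold bracketing RMS discard threshold, permil
#'   (default 7).
#' @param weighting pool-weighting mode, `"hydrogen"` (default) or
#'   `"abundance"`; see [pool_fractionation()].
#' @param rms_default instrument RMS floor (permil) used if the sequence
#'   contains no passing standards to estimate it from (default 5.5).
#' @return object of class `study_reduction`: list with data.frames
#'   `fractionation` (per cell x compound: percent abundance, delta vs
#'   V-SMOW, eps vs water, sems, n), `eps_total` (per cell), `qc` tables,
#'   the `methyl_calibration`, and `session_rms`.
#' @export
reduce_study <- function(peaks, samples, standards, qc_threshold = 7,
                         weighting = c("hydrogen", "abundance"),
                         rms_default = 5.5) {
  weighting <- match.arg(weighting)
  pk <- read_peak_table(peaks)
  smp <- read_samples(samples)
  std <- read_standards(standards)
  inj <- injections(pk)

  mix <- std[std$standard_name == "fame_mix", , drop = FALSE]
  if (nrow(mix) == 0) stop("reduce_study: standards table has no fame_mix rows")
  known_mix <- stats::setNames(mix$known_delta_permil, mix$compound)
  qc <- bracketing_qc(inj, known_mix, threshold = qc_threshold)
  floor_rms <- if (is.finite(qc$session_rms) && qc$session_rms > 0) {
    qc$session_rms
  } else rms_default

  ref <- std[std$standard_name == "coinjected_C24", , drop = FALSE]
  if (nrow(ref) != 1) {
    stop("reduce_study: standards table must carry exactly one coinjected_C24 row")
  }
  ref_delta <- ref$known_delta_permil
  is_compound <- ref$compound

  pass_ids <- qc$samples$injection_id[qc$samples$passed]
  roles <- vapply(inj, `[[`, character(1), "role")
  ids <- vapply(inj, `[[`, character(1), "injection_id")
  linked <- ids %in% smp$injection_id
  # biological samples are subject to the bracketing discard rule;
  # calibration standards are aggregated across the whole session
  smp_inj <- inj[roles == "sample" & linked & ids %in% pass_ids]
  if (length(smp_inj) == 0) {
    stop("reduce_study: no sample injections pass bracketing QC")
  }

  # --- methyl calibration from derivatized standards in the sequence ----
  mst <- std[std$n_methyl_H_added > 0 & !is.na(std$n_methyl_H_added), ,
             drop = FALSE]
  if (nrow(mst) == 0) {
    stop("reduce_study: standards table has no derivatization standards")
  }
  cal_inj <- inj[roles == "sample" & !linked]
  cal_rows <- lapply(seq_len(nrow(mst)), function(i) {
    comp <- mst$compound[i]
    vals <- unlist(lapply(cal_inj, function(x) {
      x$peaks$delta_raw_permil[x$peaks$compound == comp]
    }))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NULL)
    vs <- reference_to_vsmow(vals, ref_delta)
    agg <- aggregate_pseudoreplicates(vs, rms_floor = floor_rms)
    invt <- inventory_table(comp)
    data.frame(name = mst$standard_name[i],
               h_nonexch = invt$h_nonexch_acid,
               h_methyl_added = mst$n_methyl_H_added[i],
               known_delta_permil = mst$known_delta_permil[i],
               measured_delta_permil = agg$value,
               measured_sem_permil = agg$sem,
               stringsAsFactors = FALSE)
  })
  cal_rows <- do.call(rbind, cal_rows)
  if (is.null(cal_rows)) {
    stop("reduce_study: no derivatization-standard peaks found in the sequence")
  }
  cal <- calibrate_methyl(cal_rows)

  # --- per-cell reduction ----------------------------------------------
  meta <- smp[match(vapply(smp_inj, `[[`, character(1), "injection_id"),
                    smp$injection_id), ]
  cells <- unique(smp[, c("strain", "donor", "sulfate_mM")])
  cells <- cells[order(cells$strain, cells$donor, cells$sulfate_mM), ,
                 drop = FALSE]

  frac_rows <- list(); tot_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    in_cell <- which(meta$strain == cell$strain & meta$donor == cell$donor &
                       meta$sulfate_mM == cell$sulfate_mM)
    if (length(in_cell) == 0) next
    cinj <- smp_inj[in_cell]
    cmeta <- meta[in_cell, ]
    water <- mean(cmeta$water_delta_permil)

    # long table of sample peaks on the V-SMOW scale
    pk_long <- do.call(rbind, lapply(seq_along(cinj), function(j) {
      p <- cinj[[j]]$peaks
      p <- p[!is.na(p$delta_raw_permil) & p$compound != is_compound &
               p$compound != "" & !is.na(p$compound), , drop = FALSE]
      if (nrow(p) == 0) return(NULL)
      data.frame(bio_rep = cmeta$bio_rep[j], compound = p$compound,
                 delta_vsmow = reference_to_vsmow(p$delta_raw_permil,
                                                  ref_delta)$value,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pk_long)) next

    comps <- sort(unique(pk_long$compound))
    agg <- lapply(comps, function(cc) {
      per_bio <- lapply(split(pk_long$delta_vsmow[pk_long$compound == cc],
                              pk_long$bio_rep[pk_long$compound == cc]),
                        aggregate_pseudoreplicates, rms_floor = floor_rms)
      v <- vapply(per_bio, function(d) d$value, numeric(1))
      s <- vapply(per_bio, function(d) d$sem, numeric(1))
      nb <- length(v)
      sem <- if (nb > 1) {
        max(stats::sd(v) / sqrt(nb), sqrt(sum(s^2)) / nb)
      } else s
      delta_value(mean(v), sem = sem,
                  n = sum(vapply(per_bio, function(d) d$n, integer(1))))
    })
    names(agg) <- comps

    invt <- inventory_table(comps)
    corrected <- lapply(comps, function(cc) {
      i <- match(cc, invt$compound)
      inv <- new_hydrogen_inventory(invt$h_total_acid[i], n_carboxyl = 1L,
                                    h_primer = invt$h_primer[i], label = cc)
      correct_methyl(agg[[cc]], inv, cal)
    })
    names(corrected) <- comps
    # split each per-lipid sem into its independent (measurement) part and
    # the methyl-calibration part, which is shared across all lipids and
    # must propagate linearly through the pool weights
    sem_ind <- vapply(comps, function(cc) {
      i <- match(cc, invt$compound)
      invt$h_fame[i] * agg[[cc]]$sem / invt$h_nonexch_acid[i]
    }, numeric(1))
    sem_cal <- vapply(comps, function(cc) {
      i <- match(cc, invt$compound)
      invt$h_methyl_added[i] * cal$delta_methyl$sem / invt$h_nonexch_acid[i]
    }, numeric(1))

    # abundances: percent of total per injection, averaged over injections
    prof <- profile_from_injections(cinj, is_compound)
    pct <- prof$percent[match(comps, prof$compound)]

    eps <- lapply(comps, function(cc) fractionation(corrected[[cc]], water))
    frac_rows[[length(frac_rows) + 1]] <- data.frame(
      strain = cell$strain, donor = cell$donor, sulfate_mM = cell$sulfate_mM,
      compound = comps,
      percent = pct,
      delta_vsmow = vapply(corrected, function(d) d$value, numeric(1)),
      delta_sem = vapply(corrected, function(d) d$sem, numeric(1)),
      n = vapply(corrected, function(d) d$n, integer(1)),
      eps = vapply(eps, function(e) e$eps, numeric(1)),
      eps_sem = vapply(eps, function(e) e$sem, numeric(1)),
      water_delta_permil = water,
      stringsAsFactors = FALSE
    )

    pool <- pool_fractionation(
      data.frame(compound = comps, abundance = pct,
                 delta_permil = vapply(corrected, function(d) d$value,
                                       numeric(1)),
                 sem_permil = sem_ind, sem_corr_permil = sem_cal,
                 stringsAsFactors = FALSE),
      water, weighting = weighting)
    tot_rows[[length(tot_rows) + 1]] <- data.frame(
      strain = cell$strain, donor = cell$donor, sulfate_mM = cell$sulfate_mM,
      delta_total = pool$delta_total$value,
      delta_total_sem = pool$delta_total$sem,
      eps_total = pool$eps_total$eps,
      eps_total_sem = pool$eps_total$sem,
      n_lipids = pool$delta_total$n,
      water_delta_permil = water,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(fractionation = do.call(rbind, frac_rows),
         eps_total = do.call(rbind, tot_rows),
         qc = qc, calibration = cal, session_rms = floor_rms,
         weighting = weighting),
    class = "study_reduction"
  )
}

# percent abundance per compound from a set of injections sharing a cell:
# per injection, amount_i proportional to area_i / area_IS; the internal
# standard is excluded from the total; percents averaged across injections
profile_from_injections <- function(cinj, is_compound) {
  per_inj <- lapply(cinj, function(x) {
    p <- x$peaks[!is.na(x$peaks$area), , drop = FALSE]
    is_area <- p$area[p$compound == is_compound]
    if (length(is_area) != 1 || is_area <= 0) return(NULL)
    a <- p[p$compound != is_compound & !is.na(p$compound) & p$compound != "", ]
    if (nrow(a) == 0) return(NULL)
    data.frame(compound = a$compound,
               percent = 100 * a$area / sum(a$area),
               stringsAsFactors = FALSE)
  })
  per_inj <- per_inj[!vapply(per_inj, is.null, logical(1))]
  if (length(per_inj) == 0) {
    stop("profile_from_injections: no quantifiable injections (missing internal standard?)")
  }
  long <- do.call(rbind, per_inj)
  m <- tapply(long$percent, long$compound, mean)
  out <- data.frame(compound = names(m), percent = as.numeric(m),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$percent / sum(out$percent)
  out[order(out$compound), , drop = FALSE]
}

#' @export
print.study_reduction <- function(x, ...) {
  cat("<study_reduction>\n")
  cat(sprintf("  %d cell(s), %d per-lipid rows; weighting: %s\n",
              nrow(x$eps_total), nrow(x$fractionation), x$weighting))
  cat(sprintf("  session RMS %.2f ‰; methyl delta %.1f ‰ (spread %.1f ‰)\n",
              x$session_rms, x$calibration$delta_methyl$value,
              x$calibration$spread))
  cat(sprintf("  eps_total range: %.0f to %.0f ‰\n",
              min(x$eps_total$eps_total), max(x$eps_total$eps_total)))
  invisible(x)
}

#' Write reduction outputs as CSV
#'
#' Emits `fractionation.csv`, `eps_total.csv` and `qc.csv` in `dir`.
#'
#' @param x a `study_reduction`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reduction <- function(x, dir) {
  stopifnot(inherits(x, "study_reduction"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv15(x$fractionation, file.path(dir, "fractionation.csv"))
  write_csv15(x$eps_total, file.path(dir, "eps_total.csv"))
  qc <- merge(x$qc$standards, x$qc$samples, all = TRUE)
  write_csv15(qc, file.path(dir, "qc.csv"))
  invisible(dir)
}
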