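# Raw FAME delta-2H -> free-acid delta-2H vs V-SMOW.
#
# The derivatization methanol adds three hydrogens per acid group whose
# isotopic composition must be removed by mass balance. The methyl delta is
# first estimated from derivatized standards of known free-acid
# composition, then subtracted from every sample FAME:
#   calibration: d_Me = (h_fame * d_meas - h_nonexch * d_known) / h_methyl
#   correction:  d_FA = (h_fame * d_FAME - h_methyl * d_Me) / h_nonexch
# Both are linear in delta, so the forward/backward round trip is exact.

#' Calibrate the methyl-hydrogen delta from derivatized standards
#'
#' Each standard of known free-acid (non-exchangeable) composition,
#' measured after derivatization, yields one estimate of the methanol
#' methyl-hydrogen delta by mass balance; estimates are combined as their
#' unweighted mean. A spread above 20 permil between standards triggers a
#' warning but not a failure.
#'
#' @param standards data.frame with one row per standard: columns `name`,
#'   `h_nonexch` (non-exchangeable H of the free acid), `h_methyl_added`,
#'   `known_delta_permil` (free acid, vs V-SMOW), `measured_delta_permil`
#'   (derivatized, vs V-SMOW), optional `measured_sem_permil`.
#' @return object of class `methyl_calibration`: list with `delta_methyl`
#'   (a [delta_value]), `per_standard` (data.frame of per-standard
#'   estimates), and `spread` (max pairwise disagreement, permil).
#' @examples
#' calibrate_methyl(data.frame(
#'   name = "myristic", h_nonexch = 27, h_methyl_added = 3,
#'   known_delta_permil = -230, measured_delta_permil = -250))
#' @export
calibrate_methyl <- function(standards) {
  if (!is.data.frame(standards) || nrow(standards) == 0) {
    stop("calibrate_methyl: at least one standard is required")
  }
  check_columns(standards,
                c("name", "h_nonexch", "h_methyl_added",
                  "known_delta_permil", "measured_delta_permil"),
                "methyl standards")
  if (any(standards$h_methyl_added <= 0)) {
    stop("calibrate_methyl: h_methyl_added must be positive")
  }
  h_fame <- standards$h_nonexch + standards$h_methyl_added
  f_meas <- permil_to_fraction(standards$measured_delta_permil)
  f_known <- permil_to_fraction(standards$known_delta_permil)
  est <- (h_fame * f_meas - standards$h_nonexch * f_known) /
    standards$h_methyl_added
  sem_meas <- if ("measured_sem_permil" %in% names(standards)) {
    standards$measured_sem_permil / 1000
  } else rep(0, nrow(standards))
  est_sem <- h_fame * sem_meas / standards$h_methyl_added
  m <- mean(est)
  # uncertainty of the mean: propagated measurement part plus scatter
  k <- length(est)
  sem <- sqrt(sum(est_sem^2)) / k
  if (k > 1) sem <- max(sem, stats::sd(est) / sqrt(k))
  spread <- if (k > 1) diff(range(est)) * 1000 else 0
  if (spread > 20) {
    warning(sprintf(
      "methyl calibration standards disagree by %.1f permil (> 20)", spread))
  }
  structure(
    list(delta_methyl = delta_value(fraction_to_permil(m),
                                    sem = fraction_to_permil(sem), n = k),
         per_standard = data.frame(name = standards$name,
                                   estimate_permil = est * 1000),
         spread = spread),
    class = "methyl_calibration"
  )
}

#' @export
print.methyl_calibration <- function(x, ...) {
  cat(sprintf("<methyl_calibration> delta_Me = %.1f ‰ (sem %.1f, %d standard(s), spread %.1f ‰)\n",
              x$delta_methyl$value, x$delta_methyl$sem,
              nrow(x$per_standard), x$spread))
  invisible(x)
}

#' Remove methyl hydrogen from a FAME delta by mass balance
#'
#' @param delta_fame [delta_value] (or numeric permil) of the methyl ester
#'   vs V-SMOW.
#' @param inventory a [hydrogen_inventory()] of the underlying acid.
#' @param cal a `methyl_calibration` (or a numeric methyl delta in permil).
#' @return [delta_value] of the free acid's non-exchangeable hydrogen vs
#'   V-SMOW, with first-order propagated sem.
#' @examples
#' correct_methyl(-180, hydrogen_inventory("n-C16:0"), -430)  # -155.8
#' @export
correct_methyl <- function(delta_fame, inventory, cal) {
  stopifnot(inherits(inventory, "hydrogen_inventory"))
  if (inventory$h_nonexch_acid <= 0) {
    stop("correct_methyl: no non-exchangeable hydrogen")
  }
  d <- as_delta_value(delta_fame)
  me <- if (inherits(cal, "methyl_calibration")) cal$delta_methyl
        else as_delta_value(cal)
  fF <- permil_to_fraction(d$value); sF <- d$sem / 1000
  fM <- permil_to_fraction(me$value); sM <- me$sem / 1000
  hf <- inventory$h_fame; hm <- inventory$h_methyl_added
  hn <- inventory$h_nonexch_acid
  f <- (hf * fF - hm * fM) / hn
  se <- sqrt((hf * sF)^2 + (hm * sM)^2) / hn
  delta_value(fraction_to_permil(f), sem = fraction_to_permil(se),
              n = d$n, reference = "V-SMOW")
}

#' Recombine a free-acid delta with the methyl delta (forward mass balance)
#'
#' Exact inverse of [correct_methyl()]; used by the synthetic-study
#' generator and by round-trip checks.
#'
#' @inheritParams correct_methyl
#' @param delta_acid free-acid non-exchangeable delta (permil vs V-SMOW).
#' @return numeric FAME delta in permil.
#' @export
forward_methyl <- function(delta_acid, inventory, cal) {
  stopifnot(inherits(inventory, "hydrogen_inventory"))
  me <- if (inherits(cal, "methyl_calibration")) cal$delta_methyl$value
        else if (inherits(cal, "delta_value")) cal$value else cal
  fA <- permil_to_fraction(delta_acid)
  fM <- permil_to_fraction(me)
  hn <- inventory$h_nonexch_acid; hm <- inventory$h_methyl_added
  fraction_to_permil((hn * fA + hm * fM) / inventory$h_fame)
}

#' Bracketing-standard quality control
#'
#' Computes, for every standard-mix injection, the root-mean-square
#' disagreement between its measured deltas and the mix's known values,
#' and passes each sample injection only if the nearest preceding and
#' nearest following standard-mix injections (in run order) both have an
#' RMS at or below the threshold. Samples at the sequence edges without a
#' bracket on both sides fail.
#'
#' @param injection_list list of `injection` objects (from
#'   [injections()]), ordered by run order.
#' @param known_mix named numeric vector: known delta (permil vs V-SMOW)
#'   per mix compound.
#' @param threshold RMS discard threshold in permil (default 7).
#' @return object of class `bracketing_qc`: list with `standards`
#'   (data.frame: injection_id, run_order, rms_permil, passed), `samples`
#'   (data.frame: injection_id, run_order, passed, reason), and
#'   `session_rms` (pooled RMS over passing standard injections, permil).
#' @export
bracketing_qc <- function(injection_list, known_mix, threshold = 7) {
  roles <- vapply(injection_list, `[[`, character(1), "role")
  ro <- vapply(injection_list, `[[`, numeric(1), "run_order")
  std_idx <- which(roles == "fame_mix_standard")
  if (length(std_idx) == 0) {
    stop("bracketing_qc: no standard-mix injections in sequence")
  }
  sq_dev <- list()
  std <- do.call(rbind, lapply(std_idx, function(i) {
    p <- injection_list[[i]]$peaks
    k <- known_mix[p$compound]
    dev <- p$delta_raw_permil - k
    dev <- dev[!is.na(dev)]
    if (length(dev) == 0) {
      stop(sprintf("bracketing_qc: standard injection %s shares no compound with the known mix",
                   injection_list[[i]]$injection_id))
    }
    rms <- sqrt(mean(dev^2))
    sq_dev[[length(sq_dev) + 1]] <<- if (rms <= threshold) dev^2 else NULL
    data.frame(injection_id = injection_list[[i]]$injection_id,
               run_order = injection_list[[i]]$run_order,
               rms_permil = rms, passed = rms <= threshold,
               stringsAsFactors = FALSE)
  }))
  pooled <- unlist(sq_dev)
  session_rms <- if (length(pooled) > 0) sqrt(mean(pooled)) else NA_real_
  smp_idx <- which(roles == "sample")
  samples <- do.call(rbind, lapply(smp_idx, function(i) {
    before <- std[std$run_order < ro[i], , drop = FALSE]
    after <- std[std$run_order > ro[i], , drop = FALSE]
    if (nrow(before) == 0 || nrow(after) == 0) {
      return(data.frame(injection_id = injection_list[[i]]$injection_id,
                        run_order = ro[i], passed = FALSE,
                        reason = "unbracketed", stringsAsFactors = FALSE))
    }
    b <- before[which.max(before$run_order), ]
    a <- after[which.min(after$run_order), ]
    ok <- b$passed && a$passed
    data.frame(injection_id = injection_list[[i]]$injection_id,
               run_order = ro[i], passed = ok,
               reason = if (ok) "" else "bracket RMS above threshold",
               stringsAsFactors = FALSE)
  }))
  if (is.null(samples)) {
    samples <- data.frame(injection_id = character(0), run_order = numeric(0),
                          passed = logical(0), reason = character(0))
  }
  structure(list(standards = std, samples = samples,
                 session_rms = session_rms, threshold = threshold),
            class = "bracketing_qc")
}

#' @export
print.bracketing_qc <- function(x, ...) {
  cat(sprintf("<bracketing_qc> threshold %.1f ‰; %d/%d standards pass; %d/%d samples pass; session RMS %.2f ‰\n",
              x$threshold, sum(x$standards$passed), nrow(x$standards),
              sum(x$samples$passed), nrow(x$samples), x$session_rms))
  invisible(x)
}

#' Pool-weighted total delta and fractionation of a fatty-acid pool
#'
#' The pool delta is the weighted mean of per-lipid deltas; weights are
#' relative abundance times the per-molecule non-exchangeable hydrogen
#' count (mode `"hydrogen"`, the default hydrogen-mass-balance reading of a
#' mass-weighted average) or abundance alone (mode `"abundance"`). Lipids
#' with a missing delta are excluded (and returned in `excluded`). The
#' total fractionation follows from [fractionation()] against the medium
#' water. Weights are treated as exact in the error propagation.
#'
#' @param items data.frame with columns `compound`, `abundance` (>= 0, any
#'   consistent unit), `delta_permil` (vs V-SMOW), optional `sem_permil`
#'   (independent, per-lipid), optional `sem_corr_permil` (an uncertainty
#'   component fully correlated across lipids, e.g. from a shared methyl
#'   calibration: it propagates linearly through the weights rather than
#'   in quadrature), optional `h_nonexch` (looked up from the compound
#'   grammar/library when absent).
#' @param delta_water [delta_value] (or numeric permil) of the medium
#'   water.
#' @param weighting `"hydrogen"` or `"abundance"`.
#' @return list with `delta_total` ([delta_value]), `eps_total`
#'   (`fractionation_result`), `weights` (normalized), `excluded`
#'   (character vector of compounds without a delta).
#' @export
pool_fractionation <- function(items, delta_water,
                               weighting = c("hydrogen", "abundance")) {
  weighting <- match.arg(weighting)
  check_columns(items, c("compound", "abundance", "delta_permil"),
                "pool items")
  if (any(items$abundance < 0)) {
    stop("pool_fractionation: abundances must be >= 0")
  }
  excluded <- items$compound[is.na(items$delta_permil)]
  use <- items[!is.na(items$delta_permil), , drop = FALSE]
  if (nrow(use) == 0 || all(use$abundance == 0)) {
    stop("pool_fractionation: no lipids with positive abundance and a delta")
  }
  if (!"h_nonexch" %in% names(use)) {
    use$h_nonexch <- inventory_table(use$compound)$h_nonexch_acid
  }
  w <- switch(weighting,
              hydrogen = use$abundance * use$h_nonexch,
              abundance = use$abundance)
  w <- w / sum(w)
  f <- permil_to_fraction(use$delta_permil)
  s <- if ("sem_permil" %in% names(use)) {
    ifelse(is.na(use$sem_permil), 0, use$sem_permil) / 1000
  } else rep(0, nrow(use))
  s_corr <- if ("sem_corr_permil" %in% names(use)) {
    ifelse(is.na(use$sem_corr_permil), 0, use$sem_corr_permil) / 1000
  } else rep(0, nrow(use))
  f_tot <- sum(w * f)
  # independent parts add in quadrature; the shared component adds linearly
  s_tot <- sqrt(sum((w * s)^2) + sum(w * s_corr)^2)
  delta_total <- delta_value(fraction_to_permil(f_tot),
                             sem = fraction_to_permil(s_tot),
                             n = nrow(use))
  list(delta_total = delta_total,
       eps_total = fractionation(delta_total, delta_water),
       weights = stats::setNames(w, use$compound),
       excluded = excluded)
}
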