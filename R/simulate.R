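# Seeded synthetic-study generator: emits the full set of pipeline inputs
# (peak tables, sample sheet, standards, OD curves) together with the
# underlying truth, so every stage of the reduction is testable end to end.
#
# Default study conditions: 3 strains x 5 substrate conditions, 2
# biological x 3-6 technical (pseudoreplicate) injections, 5.5 permil
# Gaussian measurement noise on deltas, 2% relative lognormal noise on
# peak areas, bracketing standard-mix injections every <= 6 samples, and
# two-phase (diauxic) OD curves for the mutants on malate/fumarate.

# run body with a private RNG stream, restoring the caller's RNG state
with_stream <- function(seed, body) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  body()
}

# compound panel: isotopic offsets (permil, eps space, relative to the
# cell's pool value) encode the observed orderings -- unsaturated below
# saturated homologs, anteiso below straight chains, iso-C18:0 the least
# depleted; base percents are a Desulfovibrio-like profile
panel <- function() {
  data.frame(
    compound = c("n-C14:0", "i-C15:0", "a-C15:0", "n-C15:0", "i-C16:0",
                 "n-C16:1", "n-C16:0", "i-C17:1", "a-C17:1", "i-C17:0",
                 "a-C17:0", "n-C17:0", "n-C18:1", "n-C18:0", "i-C18:0"),
    eps_offset = c(5, 8, -15, 5, 8, -30, 10, -20, -35, 8, -18, 6, -12, 8, 45),
    base_pct = c(2, 18, 8, 2, 3, 8, 22, 4, 3, 6, 10, 2, 5, 5, 2),
    stringsAsFactors = FALSE
  )
}

# invented but fixed instrument constants of the synthetic study
SIM_CONST <- list(
  c24_known = -232.2,        # coinjected methyl tetracosanoate, vs V-SMOW
  delta_methyl = -160,       # derivatization methanol methyl H, vs V-SMOW
  myristic_known = -230.5,   # free-acid non-exchangeable H
  phthalic_known = -95.3,
  mix_compounds = c("n-C14:0", "n-C15:0", "n-C16:0", "n-C17:0", "n-C18:0",
                    "n-C20:0", "n-C22:0", "n-C24:0"),
  mix_known = c(-231.1, -208.4, -186.2, -240.7, -171.9, -199.5, -145.8,
                -232.2),
  is_area = 20000, sample_area_scale = 800, mix_area = 12000
)

default_conditions <- function() {
  strains <- c("wild-type", "nfnA-2", "nfnB-2")
  cond <- data.frame(
    donor = c("pyruvate", "malate", "fumarate", "fumarate", "pyruvate"),
    sulfate_mM = c(40, 40, 40, 0, 0)
  )
  out <- merge(data.frame(strain = strains), cond)
  out[order(out$strain, out$donor, out$sulfate_mM), , drop = FALSE]
}

# retention model: invented FAME retention indices on a 5%-phenyl column,
# mapped to minutes through the linear alkane ramp
sim_ri <- function(compound) {
  fa <- parse_lipid_label(compound)
  100 * fa$n_carbon + 324 -
    switch(fa$branching, normal = 0, iso = 64, anteiso = 54) -
    25 * fa$n_double_bonds
}

sim_rt <- function(ri) 1.5 + (ri / 100 - 8) * 1.55

sim_ladder <- function() {
  data.frame(carbon = 12:30, rt_min = sim_rt(100 * (12:30)))
}

#' Generate a complete synthetic study
#'
#' Builds a seeded mock measurement campaign with the statistical
#' structure the reduction assumes: per-cell true per-lipid
#' fractionations with consistent isotopic ordering, forward
#' methyl mass balance onto the measured FAME scale, referencing against
#' the coinjected standard, bracketing standard-mix injections every six
#' samples, derivatized calibration standards, an alkane ladder, and mono-
#' or diauxic logistic OD curves. Regeneration with the same seed is
#' identical; the caller's RNG state is untouched.
#'
#' @param seed master seed; per-file sub-streams are derived from it.
#' @param n_bio biological replicates per cell (default 2).
#' @param n_pseudo range of pseudoreplicate injections per extract
#'   (default `c(3, 6)`).
#' @param noise_permil Gaussian measurement noise on deltas (sd, permil;
#'   default 5.5, the session RMS of the emulated instrument).
#' @param abund_rel_noise relative lognormal noise on peak areas
#'   (default 0.02).
#' @param od_rel_noise relative Gaussian noise on OD readings
#'   (default 0.01).
#' @param conditions data.frame of strain/donor/sulfate_mM cells (default:
#'   all 15).
#' @param ordering_flags impose the isotopic orderings (unsaturated <
#'   saturated, anteiso < straight, iso-C18:0 maximal) on the truth
#'   (default TRUE; when FALSE the offsets are shuffled per cell).
#' @param out_dir optional directory; when given, writes `peaks.csv`,
#'   `samples.csv`, `standards.csv`, `od.csv`, `truth_lipids.csv`,
#'   `truth_growth.csv`, `truth_global.csv`.
#' @return object of class `synthetic_study`: list with data.frames
#'   `peaks`, `samples`, `standards`, `od`, `truth_lipids`,
#'   `truth_growth`, `truth_global`.
#' @export
generate_study <- function(seed = 1, n_bio = 2, n_pseudo = c(3, 6),
                           noise_permil = 5.5, abund_rel_noise = 0.02,
                           od_rel_noise = 0.01, conditions = NULL,
                           ordering_flags = TRUE, out_dir = NULL) {
  if (is.null(conditions)) conditions <- default_conditions()
  check_columns(conditions, c("strain", "donor", "sulfate_mM"), "conditions")
  all15 <- default_conditions()
  ok <- paste(conditions$strain, conditions$donor, conditions$sulfate_mM) %in%
    paste(all15$strain, all15$donor, all15$sulfate_mM)
  if (!all(ok)) {
    stop("generate_study: conditions outside the 15 strain x condition cells")
  }
  pan <- panel()
  inv <- inventory_table(pan$compound)
  n_cell <- nrow(conditions)

  # ---- truth stream ----------------------------------------------------
  truth <- with_stream(seed * 13 + 101, function() {
    lip <- list(); grw <- list()
    for (i in seq_len(n_cell)) {
      cc <- conditions[i, ]
      water <- stats::runif(1, -60, -50)
      eps_target <- stats::runif(1, -175, -55)
      off <- pan$eps_offset
      if (!ordering_flags) off <- sample(off)
      jit <- stats::runif(nrow(pan), -3, 3)
      pct <- pan$base_pct
      defect <- cc$strain != "wild-type" && cc$donor %in% c("malate", "fumarate")
      if (defect) {
        shift <- stats::setNames(rep(0, nrow(pan)), pan$compound)
        shift[c("a-C17:0", "a-C15:0")] <- c(6, 2)
        shift[c("n-C16:0", "i-C15:0", "n-C18:0")] <- c(-4, -2, -2)
        pct <- pmax(pct + shift, 0.2)
      }
      pct <- 100 * pct / sum(pct)
      w <- pct * inv$h_nonexch_acid
      base <- eps_target - sum(w * (off + jit)) / sum(w)
      eps_lipid <- base + off + jit
      delta_lipid <- fraction_to_permil(
        (1 + permil_to_fraction(eps_lipid)) *
          (1 + permil_to_fraction(water)) - 1)
      lip[[i]] <- data.frame(
        strain = cc$strain, donor = cc$donor, sulfate_mM = cc$sulfate_mM,
        compound = pan$compound, eps_lipid = eps_lipid,
        delta_vsmow = delta_lipid, abundance_pct = pct,
        water_delta_permil = water, eps_total = eps_target,
        stringsAsFactors = FALSE)

      mu <- stats::runif(1, 0.007, 0.172)
      if (defect) {
        ph <- data.frame(phase = 1:2, mu = c(mu * 1.4, mu * 0.5),
                         A = c(0.30, 0.20), lambda = NA_real_)
      } else {
        ph <- data.frame(phase = 1, mu = mu,
                         A = stats::runif(1, 0.5, 0.8), lambda = NA_real_)
      }
      ph$lambda[1] <- stats::runif(1, 2, 8)
      if (nrow(ph) == 2) {
        t1 <- ph$lambda[1] + 2.5 * ph$A[1] / ph$mu[1]
        ph$lambda[2] <- t1 + 0.6 * ph$A[2] / ph$mu[2]
      }
      grw[[i]] <- cbind(strain = cc$strain, donor = cc$donor,
                        sulfate_mM = cc$sulfate_mM, ph,
                        mu_avg = sum(ph$mu * ph$A) / sum(ph$A),
                        diauxic = nrow(ph) == 2)
    }
    list(lipids = do.call(rbind, lip), growth = do.call(rbind, grw))
  })

  # ---- standards table (known compositions, no RNG) --------------------
  standards <- rbind(
    data.frame(standard_name = "coinjected_C24", compound = "n-C24:0",
               known_delta_permil = SIM_CONST$c24_known, n_methyl_H_added = 0),
    data.frame(standard_name = "myristic_acid", compound = "n-C14:0",
               known_delta_permil = SIM_CONST$myristic_known,
               n_methyl_H_added = 3),
    data.frame(standard_name = "phthalic_acid", compound = "phthalic_acid",
               known_delta_permil = SIM_CONST$phthalic_known,
               n_methyl_H_added = 6),
    data.frame(standard_name = "fame_mix", compound = SIM_CONST$mix_compounds,
               known_delta_permil = SIM_CONST$mix_known, n_methyl_H_added = 0)
  )

  # ---- injection sequence (peaks stream) -------------------------------
  seq_data <- with_stream(seed * 13 + 202, function() {
    rows <- list(); samples <- list()
    run <- 0L; n_inj <- 0L; since_mix <- 0L
    add <- function(df) rows[[length(rows) + 1]] <<- df
    next_id <- function(prefix) {
      n_inj <<- n_inj + 1L
      sprintf("%s%04d", prefix, n_inj)
    }
    mix_injection <- function() {
      run <<- run + 1L
      id <- next_id("MIX")
      add(data.frame(
        injection_id = id, run_order = run, role = "fame_mix_standard",
        compound = SIM_CONST$mix_compounds,
        rt_min = sim_rt(vapply(SIM_CONST$mix_compounds, sim_ri, numeric(1))),
        area = SIM_CONST$mix_area,
        delta_raw_permil = SIM_CONST$mix_known +
          stats::rnorm(length(SIM_CONST$mix_known), 0, noise_permil),
        delta_sem_permil = NA_real_, h3_factor = 2.98,
        stringsAsFactors = FALSE))
      since_mix <<- 0L
    }

    # alkane ladder first
    run <- run + 1L
    lad <- sim_ladder()
    add(data.frame(
      injection_id = next_id("ALK"), run_order = run, role = "alkane_ladder",
      compound = sprintf("alkane-C%d", lad$carbon), rt_min = lad$rt_min,
      area = 5000, delta_raw_permil = NA_real_, delta_sem_permil = NA_real_,
      h3_factor = 2.98, stringsAsFactors = FALSE))
    mix_injection()

    # derivatized calibration standards (3 pseudoreplicate injections)
    myr_inv <- hydrogen_inventory("n-C14:0")
    pht_inv <- polyacid_inventory(8, 6, 2, "phthalic_acid")
    myr_fame <- forward_methyl(SIM_CONST$myristic_known, myr_inv,
                               SIM_CONST$delta_methyl)
    pht_fame <- forward_methyl(SIM_CONST$phthalic_known, pht_inv,
                               SIM_CONST$delta_methyl)
    for (r in 1:3) {
      run <- run + 1L
      id <- next_id("STD")
      raw <- vsmow_to_reference(c(myr_fame, pht_fame), SIM_CONST$c24_known)
      add(data.frame(
        injection_id = id, run_order = run, role = "sample",
        compound = c("n-C14:0", "phthalic_acid", "n-C24:0"),
        rt_min = c(sim_rt(sim_ri("n-C14:0")), 9.8, sim_rt(sim_ri("n-C24:0"))),
        area = c(9000, 9000, SIM_CONST$is_area),
        delta_raw_permil = c(raw$value + stats::rnorm(2, 0, noise_permil), 0),
        delta_sem_permil = NA_real_, h3_factor = 2.98,
        stringsAsFactors = FALSE))
      since_mix <- since_mix + 1L
    }
    mix_injection()

    # sample injections per cell x biological replicate
    pan_rt <- sim_rt(vapply(pan$compound, sim_ri, numeric(1)))
    fame_true <- function(lip) {
      vapply(seq_len(nrow(lip)), function(k) {
        i <- match(lip$compound[k], inv$compound)
        invk <- new_hydrogen_inventory(inv$h_total_acid[i], 1L,
                                       inv$h_primer[i], lip$compound[k])
        forward_methyl(lip$delta_vsmow[k], invk, SIM_CONST$delta_methyl)
      }, numeric(1))
    }
    for (i in seq_len(n_cell)) {
      cc <- conditions[i, ]
      lip <- truth$lipids[truth$lipids$strain == cc$strain &
                            truth$lipids$donor == cc$donor &
                            truth$lipids$sulfate_mM == cc$sulfate_mM, ]
      fame_vsmow <- fame_true(lip)
      raw_true <- vsmow_to_reference(fame_vsmow, SIM_CONST$c24_known)$value
      for (b in seq_len(n_bio)) {
        np <- if (n_pseudo[1] == n_pseudo[length(n_pseudo)]) n_pseudo[1] else {
          sample(seq(n_pseudo[1], n_pseudo[length(n_pseudo)]), 1)
        }
        for (p in seq_len(np)) {
          if (since_mix >= 6L) mix_injection()
          run <- run + 1L
          id <- next_id("SMP")
          areas <- SIM_CONST$sample_area_scale * lip$abundance_pct *
            if (abund_rel_noise > 0) {
              stats::rlnorm(nrow(lip), -abund_rel_noise^2 / 2, abund_rel_noise)
            } else 1
          deltas <- raw_true +
            if (noise_permil > 0) stats::rnorm(nrow(lip), 0, noise_permil)
            else 0
          add(data.frame(
            injection_id = id, run_order = run, role = "sample",
            compound = c(lip$compound, "n-C24:0"),
            rt_min = c(pan_rt, sim_rt(sim_ri("n-C24:0"))),
            area = c(areas, SIM_CONST$is_area),
            delta_raw_permil = c(deltas, 0),
            delta_sem_permil = NA_real_, h3_factor = 2.98,
            stringsAsFactors = FALSE))
          samples[[length(samples) + 1]] <- data.frame(
            injection_id = id, strain = cc$strain, donor = cc$donor,
            sulfate_mM = cc$sulfate_mM, bio_rep = b,
            water_delta_permil = lip$water_delta_permil[1],
            stringsAsFactors = FALSE)
          since_mix <- since_mix + 1L
        }
      }
    }
    mix_injection()
    list(peaks = do.call(rbind, rows), samples = do.call(rbind, samples))
  })

  # ---- OD curves (od stream) -------------------------------------------
  od <- with_stream(seed * 13 + 303, function() {
    out <- list()
    for (i in seq_len(n_cell)) {
      cc <- conditions[i, ]
      ph <- truth$growth[truth$growth$strain == cc$strain &
                           truth$growth$donor == cc$donor &
                           truth$growth$sulfate_mM == cc$sulfate_mM, ]
      t_end <- ph$lambda[nrow(ph)] + 2.5 * ph$A[nrow(ph)] / ph$mu[nrow(ph)] + 2
      times <- seq(0, t_end, length.out = 60)
      base <- 0.02
      for (b in seq_len(n_bio)) {
        odv <- base
        for (k in seq_len(nrow(ph))) {
          odv <- odv + logistic_od(times, ph$A[k], ph$mu[k], ph$lambda[k])
        }
        if (od_rel_noise > 0) {
          odv <- odv * (1 + stats::rnorm(length(odv), 0, od_rel_noise))
        }
        out[[length(out) + 1]] <- data.frame(
          strain = cc$strain, donor = cc$donor, sulfate_mM = cc$sulfate_mM,
          bio_rep = b, time_h = times, od600 = pmax(odv, 1e-4),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })

  truth_global <- data.frame(
    name = c("delta_methyl_permil", "c24_known_permil", "noise_permil",
             "abund_rel_noise", "od_rel_noise", "seed"),
    value = c(SIM_CONST$delta_methyl, SIM_CONST$c24_known, noise_permil,
              abund_rel_noise, od_rel_noise, seed))

  study <- structure(
    list(peaks = seq_data$peaks, samples = seq_data$samples,
         standards = standards, od = od,
         truth_lipids = truth$lipids, truth_growth = truth$growth,
         truth_global = truth_global),
    class = "synthetic_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d cells, %d injections (%d peak rows), %d OD points\n",
              nrow(unique(x$samples[c("strain", "donor", "sulfate_mM")])),
              length(unique(x$peaks$injection_id)), nrow(x$peaks),
              nrow(x$od)))
  invisible(x)
}

#' Write a synthetic study to CSV files
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv15(study$peaks, file.path(dir, "peaks.csv"))
  write_csv15(study$samples, file.path(dir, "samples.csv"))
  write_csv15(study$standards, file.path(dir, "standards.csv"))
  write_csv15(study$od, file.path(dir, "od.csv"))
  write_csv15(study$truth_lipids, file.path(dir, "truth_lipids.csv"))
  write_csv15(study$truth_growth, file.path(dir, "truth_growth.csv"))
  write_csv15(study$truth_global, file.path(dir, "truth_global.csv"))
  invisible(dir)
}

#' Corrupt a fraction of bracketing standards for QC testing
#'
#' Perturbs the chosen fraction of standard-mix injections so their RMS
#' against the known mix exceeds the 7 permil discard threshold (a +30
#' permil offset on every mix compound), and returns the study with a
#' manifest of the corrupted injections.
#'
#' @param study a `synthetic_study`.
#' @param fraction fraction of standard-mix injections to corrupt, in
#'   `[0, 1]`.
#' @param seed seed for the choice of injections.
#' @return the modified study; corrupted injection ids in
#'   `study$qc_manifest`.
#' @export
inject_qc_failures <- function(study, fraction, seed = 1) {
  stopifnot(inherits(study, "synthetic_study"),
            fraction >= 0, fraction <= 1)
  mix_ids <- unique(study$peaks$injection_id[
    study$peaks$role == "fame_mix_standard"])
  n_bad <- round(fraction * length(mix_ids))
  bad <- if (n_bad == 0) character(0) else {
    with_stream(seed * 13 + 404, function() sort(sample(mix_ids, n_bad)))
  }
  sel <- study$peaks$injection_id %in% bad
  study$peaks$delta_raw_permil[sel] <- study$peaks$delta_raw_permil[sel] + 30
  study$qc_manifest <- bad
  study
}
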