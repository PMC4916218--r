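# One-call orchestration: simulate (or load) -> reduce -> growth -> stats,
# with a reproducible run manifest.

#' Run the full pipeline
#'
#' Either generates a synthetic study from `seed` or loads the four input
#' CSVs from `input_dir`, then runs the isotope reduction, the growth-curve
#' fits, and the profile statistics, and (optionally) writes all result
#' tables plus a run manifest with input/output checksums. Two runs with
#' the same seed and configuration produce identical outputs.
#'
#' @param seed master seed for the synthetic study (ignored when
#'   `input_dir` is given).
#' @param input_dir optional directory holding `peaks.csv`, `samples.csv`,
#'   `standards.csv`, `od.csv`.
#' @param out_dir optional output directory; when given, writes
#'   `fractionation.csv`, `eps_total.csv`, `qc.csv`, `growth.csv`,
#'   `profiles.csv`, `correlations.csv`, `rate_eps_models.csv`,
#'   `primer_inference.csv`, `summary.csv` (human-readable, permil rounded
#'   to 1), and `manifest.json`.
#' @param qc_threshold,weighting passed to [reduce_study()].
#' @param ... passed to [generate_study()].
#' @return object of class `pipeline_run`: list with `reduction`,
#'   `growth`, `stats`, `study` (synthetic runs only), `manifest`.
#' @export
run_pipeline <- function(seed = 1, input_dir = NULL, out_dir = NULL,
                         qc_threshold = 7,
                         weighting = c("hydrogen", "abundance"), ...) {
  weighting <- match.arg(weighting)
  if (is.null(input_dir)) {
    study <- generate_study(seed = seed, ...)
    peaks <- study$peaks; samples <- study$samples
    standards <- study$standards; od <- study$od
    inputs <- character(0)
  } else {
    study <- NULL
    inputs <- file.path(input_dir,
                        c("peaks.csv", "samples.csv", "standards.csv",
                          "od.csv"))
    for (f in inputs) {
      if (!file.exists(f)) {
        stop(sprintf("pipeline: missing input file %s", basename(f)))
      }
    }
    peaks <- inputs[1]; samples <- inputs[2]; standards <- inputs[3]
    od <- inputs[4]
  }
  reduction <- reduce_study(peaks, samples, standards,
                            qc_threshold = qc_threshold,
                            weighting = weighting)
  growth <- fit_growth_curves(od)
  stats_out <- profile_stats(reduction, growth)

  manifest <- list(
    seed = if (is.null(input_dir)) seed else NA,
    qc_threshold = qc_threshold, weighting = weighting,
    n_cells = nrow(reduction$eps_total),
    n_injections_pass = sum(reduction$qc$samples$passed),
    n_injections_fail = sum(!reduction$qc$samples$passed),
    session_rms_permil = reduction$session_rms,
    input_checksums = if (length(inputs) > 0) {
      as.list(tools::md5sum(inputs))
    } else NULL
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reduction(reduction, out_dir)
    write_csv15(growth, file.path(out_dir, "growth.csv"))
    write_csv15(stats_out$profiles, file.path(out_dir, "profiles.csv"))
    utils::write.csv(round(stats_out$correlations, 4),
                     file.path(out_dir, "correlations.csv"))
    if (!is.null(stats_out$models)) {
      write_csv15(summary(stats_out$models),
                  file.path(out_dir, "rate_eps_models.csv"))
    }
    if (!is.null(stats_out$primer)) {
      write_csv15(stats_out$primer, file.path(out_dir, "primer_inference.csv"))
    }
    # human-readable summary: permil values rounded to 1 (report precision)
    hum <- stats_out$cell_table
    hum$eps_total <- round(hum$eps_total)
    hum$eps_total_sem <- round(hum$eps_total_sem)
    hum$mu_avg <- round(hum$mu_avg, 3)
    utils::write.csv(hum, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    outs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$output_checksums <- as.list(tools::md5sum(outs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(reduction = reduction, growth = growth, stats = stats_out,
                 study = study, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$reduction)
  cat(sprintf("  growth: %d cell(s), mu_avg %.3f-%.3f /h, %d diauxic\n",
              nrow(x$growth), min(x$growth$mu_avg), max(x$growth$mu_avg),
              sum(x$growth$diauxic)))
  if (!is.null(x$stats$models)) print(x$stats$models)
  invisible(x)
}

#' Published interval-weighted growth rates
#'
#' The printed table of biomass-weighted average growth rates (per hour,
#' with standard errors) for the wild type and the two transhydrogenase
#' mutants under the five growth conditions, shipped with the package as a
#' plain-text table. Used as an input for derived quantities such as
#' mutant/wild-type rate ratios.
#'
#' @return data.frame with columns `treatment`, `donor`, `sulfate_mM`,
#'   `strain`, `mu_avg`, `mu_sem`.
#' @export
table1_growth_rates <- function() {
  path <- system.file("extdata", "table1_growth_rates.csv",
                      package = "lipid2h", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Mutant to wild-type growth-rate ratio for one treatment
#'
#' Computes `100 * mean(mutant mu_avg) / wild-type mu_avg` (percent) for a
#' treatment in a growth-rate table.
#'
#' @param rates data.frame as returned by [table1_growth_rates()] or
#'   [fit_growth_curves()] (needs `strain`, `mu_avg` and treatment
#'   columns).
#' @param donor,sulfate_mM the treatment.
#' @return percent ratio (numeric).
#' @export
mutant_wt_rate_ratio <- function(rates, donor, sulfate_mM) {
  sel <- rates$donor == donor & rates$sulfate_mM == sulfate_mM
  wt <- rates$mu_avg[sel & rates$strain == "wild-type"]
  mut <- rates$mu_avg[sel & rates$strain != "wild-type"]
  if (length(wt) != 1 || length(mut) == 0) {
    stop("mutant_wt_rate_ratio: treatment not found or incomplete")
  }
  100 * mean(mut) / wt
}

#' Read a local copy of the deposited per-lipid table
#'
#' Reads per-lipid delta-2H data from a locally provided copy of the
#' study's deposited processed data (not shipped with the package; the
#' deposit must be downloaded separately and reshaped to this schema:
#' `strain`, `donor`, `sulfate_mM`, `compound`, `delta_vsmow`,
#' `abundance_pct`, `water_delta_permil`). The mass-weighted reduction of
#' such a table reproduces the study's printed pool fractionations via
#' [pool_fractionation()].
#'
#' @param path path to the reshaped deposit CSV.
#' @return validated data.frame.
#' @export
read_deposit_lipids <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("deposited per-lipid table not found at '%s'; download the study deposit and reshape it to the documented schema",
                 path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("strain", "donor", "sulfate_mM", "compound",
                      "delta_vsmow", "abundance_pct", "water_delta_permil"),
                "deposit table")
  df
}
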