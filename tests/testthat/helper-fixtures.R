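# shared fixture builders

# minimal injection sequence: [optional leading sample] mix / samples / mix,
# with controllable standard-mix accuracy (offsets added to known values)
make_sequence <- function(known_mix, sample_deltas, mix_offsets = c(0, 0),
                          leading_sample = NULL) {
  rows <- list(); run <- 0
  add_mix <- function(off) {
    run <<- run + 1
    rows[[length(rows) + 1]] <<- data.frame(
      injection_id = sprintf("MIX%02d", run), run_order = run,
      role = "fame_mix_standard", compound = names(known_mix),
      rt_min = seq_along(known_mix) + 10, area = 1000,
      delta_raw_permil = unname(known_mix) + off,
      delta_sem_permil = NA_real_, h3_factor = 3)
  }
  add_sample <- function(deltas) {
    run <<- run + 1
    rows[[length(rows) + 1]] <<- data.frame(
      injection_id = sprintf("SMP%02d", run), run_order = run,
      role = "sample", compound = names(deltas),
      rt_min = seq_along(deltas) + 10, area = 1000,
      delta_raw_permil = unname(deltas),
      delta_sem_permil = NA_real_, h3_factor = 3)
  }
  if (!is.null(leading_sample)) add_sample(leading_sample)
  add_mix(mix_offsets[1])
  for (d in sample_deltas) add_sample(d)
  add_mix(mix_offsets[2])
  do.call(rbind, rows)
}

# noise-free two-phase (diauxic) OD curve from the package's own forward
# model, with a plateau between the phases
make_diauxic_curve <- function(mu1, mu2, A1, A2, lambda1 = 4,
                               plateau_scale = 0.6, n_points = 80,
                               od0 = 0.02) {
  t1 <- lambda1 + 2.5 * A1 / mu1
  lambda2 <- t1 + plateau_scale * A2 / mu2
  t_end <- lambda2 + 2.5 * A2 / mu2 + 2
  times <- seq(0, t_end, length.out = n_points)
  od <- od0 + lipid2h::logistic_od(times, A1, mu1, lambda1) +
    lipid2h::logistic_od(times, A2, mu2, lambda2)
  list(times = times, od = od, lambda2 = lambda2, t1 = t1,
       mu_true = (mu1 * A1 + mu2 * A2) / (A1 + A2))
}
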