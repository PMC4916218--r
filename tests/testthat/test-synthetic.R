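# the synthetic-study generator

test_that("regeneration with the same seed is identical and leaves RNG alone", {
  set.seed(999); before <- runif(1)
  a <- generate_study(seed = 4)
  b <- generate_study(seed = 4)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$od, b$od)
  expect_identical(a$truth_lipids, b$truth_lipids)
  set.seed(999)
  expect_identical(runif(1), before)
  # different seeds differ
  expect_false(identical(generate_study(seed = 5)$peaks$delta_raw_permil,
                         a$peaks$delta_raw_permil))
})

test_that("the default study has the expected design shape", {
  st <- generate_study(seed = 2)
  cells <- unique(st$samples[, c("strain", "donor", "sulfate_mM")])
  expect_equal(nrow(cells), 15)
  expect_setequal(unique(st$samples$strain),
                  c("wild-type", "nfnA-2", "nfnB-2"))
  expect_equal(sort(unique(st$samples$bio_rep)), 1:2)
  # pseudoreplicate counts all within 3..6
  np <- with(st$samples,
             tapply(injection_id, paste(strain, donor, sulfate_mM, bio_rep),
                    length))
  expect_true(all(np >= 3 & np <= 6))
  # bracketing: every sample has a standard-mix injection within 6 runs
  # on both sides
  pk <- st$peaks
  mix_runs <- sort(unique(pk$run_order[pk$role == "fame_mix_standard"]))
  smp_runs <- unique(pk$run_order[pk$role == "sample"])
  gaps <- vapply(smp_runs, function(r) {
    before <- max(mix_runs[mix_runs < r], -Inf)
    after <- min(mix_runs[mix_runs > r], Inf)
    max(r - before, after - r)
  }, numeric(1))
  expect_true(all(is.finite(gaps) & gaps <= 7))
  # an alkane ladder is present
  expect_true(any(pk$role == "alkane_ladder"))
  # mutants on malate/fumarate carry two truth phases
  tg <- st$truth_growth
  diaux <- unique(tg[tg$diauxic, c("strain", "donor")])
  expect_true(all(diaux$strain != "wild-type"))
  expect_true(all(diaux$donor %in% c("malate", "fumarate")))
})

test_that("truth encodes the observed isotopic orderings in every cell", {
  st <- generate_study(seed = 6)
  tl <- st$truth_lipids
  for (key in unique(paste(tl$strain, tl$donor, tl$sulfate_mM))) {
    cell <- tl[paste(tl$strain, tl$donor, tl$sulfate_mM) == key, ]
    d <- setNames(cell$delta_vsmow, cell$compound)
    expect_lt(d["n-C16:1"], d["n-C16:0"])
    expect_lt(d["a-C15:0"], d["n-C15:0"])
    expect_lt(d["a-C17:0"], d["n-C17:0"])
    expect_equal(names(which.max(d)), "i-C18:0")
  }
})

test_that("the written study round-trips through the readers", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  st <- generate_study(seed = 3, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("peaks.csv", "samples.csv", "standards.csv", "od.csv",
           "truth_lipids.csv", "truth_growth.csv", "truth_global.csv")))))
  pk <- read_peak_table(file.path(dir, "peaks.csv"))
  expect_equal(nrow(pk), nrow(st$peaks))
  expect_equal(pk$delta_raw_permil,
               st$peaks$delta_raw_permil[order(st$peaks$run_order)],
               tolerance = 1e-12)
  smp <- read_samples(file.path(dir, "samples.csv"))
  expect_equal(nrow(smp), nrow(st$samples))
})

test_that("QC corruption affects exactly the manifested injections", {
  st <- generate_study(seed = 8, noise_permil = 0, abund_rel_noise = 0,
                       od_rel_noise = 0)
  mix <- st$standards[st$standards$standard_name == "fame_mix", ]
  known <- setNames(mix$known_delta_permil, mix$compound)

  # fraction 0: unchanged
  st0 <- inject_qc_failures(st, 0)
  expect_identical(st0$peaks, st$peaks)
  expect_length(st0$qc_manifest, 0)

  # fraction 0.2: exactly the manifested standards fail QC
  st2 <- inject_qc_failures(st, 0.2, seed = 5)
  qc <- bracketing_qc(injections(read_peak_table(st2$peaks)), known)
  expect_setequal(qc$standards$injection_id[!qc$standards$passed],
                  st2$qc_manifest)

  # fraction 1: every standard fails, so every sample fails
  st1 <- inject_qc_failures(st, 1)
  qc1 <- bracketing_qc(injections(read_peak_table(st1$peaks)), known)
  expect_false(any(qc1$standards$passed))
  expect_false(any(qc1$samples$passed))
  expect_error(reduce_study(st1$peaks, st1$samples, st1$standards),
               "no sample injections pass")
})

test_that("invalid conditions are rejected", {
  expect_error(generate_study(seed = 1, conditions = data.frame(
    strain = "wild-type", donor = "lactate", sulfate_mM = 40)),
    "15 strain")
})
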