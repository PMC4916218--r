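# methyl calibration/correction, bracketing QC, pool fractionation

test_that("methyl calibration reproduces the mass-balance estimate", {
  # arithmetic oracle: (30*(-250) - 27*(-230)) / 3 = -430
  cal <- calibrate_methyl(data.frame(
    name = "myristic", h_nonexch = 27, h_methyl_added = 3,
    known_delta_permil = -230, measured_delta_permil = -250))
  expect_equal(cal$delta_methyl$value, -430, tolerance = 1e-9)

  # uniform-pool identity: measured == known implies delta_Me == known
  cal2 <- calibrate_methyl(data.frame(
    name = "x", h_nonexch = 27, h_methyl_added = 3,
    known_delta_permil = -230, measured_delta_permil = -230))
  expect_equal(cal2$delta_methyl$value, -230, tolerance = 1e-9)

  # two standards giving -430 and -436: unweighted mean -433, spread 6
  # (measured values constructed by the forward mass balance)
  two <- data.frame(
    name = c("a", "b"), h_nonexch = c(27, 4), h_methyl_added = c(3, 6),
    known_delta_permil = c(-230, -95),
    measured_delta_permil = c((3 * -430 + 27 * -230) / 30,
                              (6 * -436 + 4 * -95) / 10))
  cal3 <- calibrate_methyl(two)
  expect_equal(cal3$delta_methyl$value, -433, tolerance = 1e-9)
  expect_equal(cal3$spread, 6, tolerance = 1e-9)

  expect_error(calibrate_methyl(data.frame()), "at least one")
  expect_warning(
    calibrate_methyl(data.frame(
      name = c("a", "b"), h_nonexch = c(27, 27), h_methyl_added = c(3, 3),
      known_delta_permil = c(-230, -230),
      measured_delta_permil = c(-250, -253))),
    "disagree")
})

test_that("methyl correction inverts the forward mass balance exactly", {
  inv <- hydrogen_inventory("n-C16:0")  # h_nonexch 31, h_fame 34
  # arithmetic oracle: (34*(-180) - 3*(-430)) / 31
  out <- correct_methyl(-180, inv, -430)
  expect_equal(out$value, (34 * -180 - 3 * -430) / 31, tolerance = 1e-9)
  # uniform pool: delta_Me == delta_FAME leaves the value unchanged
  expect_equal(correct_methyl(-180, inv, -180)$value, -180, tolerance = 1e-12)
  # round trip over a grid of deltas and inventories
  for (lb in c("n-C14:0", "n-C16:1", "a-C17:0", "i-C18:0")) {
    invl <- hydrogen_inventory(lb)
    for (d in c(-260.7, -150, -31.2)) {
      fame <- forward_methyl(d, invl, -430)
      expect_equal(correct_methyl(fame, invl, -430)$value, d,
                   tolerance = 1e-12)
      expect_equal(forward_methyl(correct_methyl(fame, invl, -430)$value,
                                  invl, -430), fame, tolerance = 1e-12)
    }
  }
})

test_that("bracketing QC applies the RMS discard rule on both sides", {
  known <- setNames(rep(-200, 8), paste0("std", 1:8))
  smp <- list(SA = setNames(-150, "x"), SB = setNames(-160, "x"))

  # all standards exact: everything bracketed passes
  pk <- read_peak_table(make_sequence(known, smp))
  qc <- bracketing_qc(injections(pk), known)
  expect_true(all(qc$standards$rms_permil == 0))
  expect_true(all(qc$samples$passed))
  expect_equal(qc$session_rms, 0)

  # one compound off by 21 permil: RMS = 21/sqrt(8) > 7, samples fail
  off <- c(21, rep(0, 7))
  pk2 <- read_peak_table(make_sequence(known, smp, mix_offsets = c(0, NA)))
  pk2$delta_raw_permil[pk2$injection_id == "MIX01"] <- known + off
  pk2$delta_raw_permil[pk2$injection_id == "MIX04"] <- known
  qc2 <- bracketing_qc(injections(pk2), known)
  expect_equal(max(qc2$standards$rms_permil), 21 / sqrt(8), tolerance = 1e-9)
  expect_false(any(qc2$samples$passed))

  # a leading sample with no preceding bracket fails
  pk3 <- read_peak_table(make_sequence(known, smp,
                                       leading_sample = setNames(-150, "x")))
  qc3 <- bracketing_qc(injections(pk3), known)
  first <- qc3$samples[which.min(qc3$samples$run_order), ]
  expect_false(first$passed)
  expect_equal(first$reason, "unbracketed")

  expect_error(
    bracketing_qc(injections(read_peak_table(make_sequence(known, smp)))[3],
                  known),
    "no standard-mix")
})

test_that("lowering the QC threshold never admits more samples", {
  known <- setNames(rep(-200, 8), paste0("std", 1:8))
  set.seed(11)
  smp <- lapply(1:6, function(i) setNames(rnorm(1, -150, 5), "x"))
  pk <- make_sequence(known, smp, mix_offsets = c(2.5, 0))
  pk$delta_raw_permil[pk$role == "fame_mix_standard"] <-
    pk$delta_raw_permil[pk$role == "fame_mix_standard"] + rnorm(16, 0, 6)
  inj <- injections(read_peak_table(pk))
  prev <- NULL
  for (thr in c(12, 9, 7, 5, 3, 1)) {
    pass <- with(bracketing_qc(inj, known, threshold = thr)$samples,
                 injection_id[passed])
    if (!is.null(prev)) expect_true(all(pass %in% prev))
    prev <- pass
  }
})

test_that("pool fractionation matches an explicit hydrogen-atom enumeration", {
  # symmetric two-lipid case
  items <- data.frame(compound = c("n-C16:0", "n-C18:0"),
                      abundance = c(1, 1) , delta_permil = c(-100, -200),
                      h_nonexch = c(10, 10))
  expect_equal(pool_fractionation(items, -50)$delta_total$value, -150,
               tolerance = 1e-12)

  # single lipid: the pool is that lipid
  one <- data.frame(compound = "n-C16:0", abundance = 3.2,
                    delta_permil = -123.4)
  expect_equal(pool_fractionation(one, -50)$delta_total$value, -123.4,
               tolerance = 1e-12)

  # three lipids with unequal abundances and H counts; oracle enumerates
  # every hydrogen atom explicitly (abundance x h_nonexch copies each)
  tri <- data.frame(compound = c("n-C14:0", "n-C16:1", "a-C17:0"),
                    abundance = c(2, 3, 5), delta_permil = c(-80, -210, -145))
  hn <- c(27, 29, 33)
  atom_pool <- rep(tri$delta_permil, times = tri$abundance * hn)
  out <- pool_fractionation(cbind(tri, h_nonexch = hn), -55)
  expect_equal(out$delta_total$value, mean(atom_pool), tolerance = 1e-9)

  # abundance mode ignores H counts
  out_ab <- pool_fractionation(cbind(tri, h_nonexch = hn), -55,
                               weighting = "abundance")
  expect_equal(out_ab$delta_total$value,
               weighted.mean(tri$delta_permil, tri$abundance),
               tolerance = 1e-9)

  # pool delta always lies within the component deltas
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    it <- data.frame(compound = "x", abundance = runif(k, 0.1, 10),
                     delta_permil = runif(k, -300, 50),
                     h_nonexch = sample(20:40, k, replace = TRUE))
    dt <- pool_fractionation(it, -55)$delta_total$value
    expect_true(dt >= min(it$delta_permil) - 1e-9 &&
                  dt <= max(it$delta_permil) + 1e-9)
  }

  # missing deltas are excluded and reported; all-zero abundance errors
  mix <- data.frame(compound = c("a", "b"), abundance = c(1, 1),
                    delta_permil = c(-100, NA), h_nonexch = c(30, 30))
  res <- pool_fractionation(mix, -55)
  expect_equal(res$excluded, "b")
  expect_equal(res$delta_total$value, -100)
  expect_error(pool_fractionation(
    data.frame(compound = "a", abundance = 0, delta_permil = -100,
               h_nonexch = 30), -55), "abundance")
})
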