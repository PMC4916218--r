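# nomenclature parsing and hydrogen accounting

test_that("lipid labels parse to canonical identities and reparse idempotently", {
  fa <- parse_lipid_label("a-C17:0")
  expect_equal(fa$n_carbon, 17L)
  expect_equal(fa$branching, "anteiso")
  expect_equal(fa$n_double_bonds, 0L)

  fa2 <- parse_lipid_label("n-C16:1 Δ9")
  expect_equal(fa2$n_carbon, 16L)
  expect_equal(fa2$branching, "normal")
  expect_equal(fa2$n_double_bonds, 1L)
  expect_equal(fa2$db_position, 9L)

  # long prefixes, missing prefix, and the D alias for the delta position
  expect_equal(parse_lipid_label("iso-C15:0")$branching, "iso")
  expect_equal(parse_lipid_label("C18:1 D11")$db_position, 11L)

  for (lb in c("a-C17:0", "n-C16:1 Δ9", "i-C18:0", "n-C14:0")) {
    expect_equal(parse_lipid_label(parse_lipid_label(lb)$label)$label,
                 parse_lipid_label(lb)$label)
  }
  expect_error(parse_lipid_label("C15:9"), "unsaturation")
  expect_error(parse_lipid_label("hexadecanoate"), "cannot parse")
})

test_that("hydrogen inventories follow the CnH(2n-2d)O2 atom count", {
  # oracle: explicit atom counts of the molecular formulas
  myr <- hydrogen_inventory("n-C14:0")       # C14H28O2
  expect_equal(myr$h_total_acid, 28L)
  expect_equal(myr$h_nonexch_acid, 27L)
  expect_equal(myr$h_fame, 30L)

  c161 <- hydrogen_inventory("n-C16:1")      # C16H30O2
  expect_equal(c161$h_total_acid, 30L)
  expect_equal(c161$h_nonexch_acid, 29L)
  expect_equal(c161$h_fame, 32L)

  a17 <- hydrogen_inventory("a-C17:0")       # C17H34O2
  expect_equal(a17$h_nonexch_acid, 33L)
  expect_equal(a17$h_fame, 36L)
  expect_equal(a17$h_primer, 9L)
})

test_that("primer hydrogen follows the branch-class primer assignments", {
  expect_equal(hydrogen_inventory("n-C16:0")$h_primer, 3L)  # acetyl
  expect_equal(hydrogen_inventory("i-C16:0")$h_primer, 7L)  # isobutyryl
  expect_equal(hydrogen_inventory("i-C15:0")$h_primer, 9L)  # isovaleryl
  expect_equal(hydrogen_inventory("a-C15:0")$h_primer, 9L)  # 2-methylbutyryl
})

test_that("hydrogen-count properties hold across the plausible lipid space", {
  for (n in 4:24) {
    for (br in c("normal", "iso", "anteiso")) {
      for (d in 0:min(2, floor((n - 2) / 2))) {
        inv <- hydrogen_inventory(fatty_acid(n, br, d))
        # methylation always adds exactly 3 H
        expect_identical(inv$h_fame - inv$h_nonexch_acid, 3L)
        # one exchangeable carboxyl H
        expect_identical(inv$h_total_acid - inv$h_nonexch_acid, 1L)
        # each double bond removes exactly 2 H
        if (d > 0) {
          expect_identical(
            hydrogen_inventory(fatty_acid(n, br, d - 1))$h_total_acid -
              inv$h_total_acid, 2L)
        }
        # branching never changes counts
        expect_identical(inv$h_total_acid,
                         hydrogen_inventory(fatty_acid(n, "normal", d))$h_total_acid)
        # primer H bounded by non-exchangeable H (or undefined for acids
        # too small to retain the intact primer)
        expect_true(is.na(inv$h_primer) ||
                      inv$h_primer <= inv$h_nonexch_acid)
      }
    }
  }
})

test_that("polyacid inventories handle multiple ester groups", {
  pht <- polyacid_inventory(8, 6, 2, "phthalic acid")  # C8H6O4
  expect_equal(pht$h_nonexch_acid, 4L)
  expect_equal(pht$h_methyl_added, 6L)
  expect_equal(pht$h_fame, 10L)
  # single-acid route agrees with the fatty-acid grammar
  myr <- polyacid_inventory(14, 28, 1)
  via_fa <- hydrogen_inventory("n-C14:0")
  expect_equal(myr$h_nonexch_acid, via_fa$h_nonexch_acid)
  expect_equal(myr$h_fame, via_fa$h_fame)
  expect_error(polyacid_inventory(8, 6, 0), "n_carboxyl")
  expect_error(polyacid_inventory(2, 1, 2), "fewer hydrogens")
})

test_that("the packaged compound library is self-consistent", {
  lib <- compound_library()
  expect_true(all(c("a-C17:0", "n-C16:1", "phthalic_acid", "n-C24:0") %in%
                    lib$compound))
  expect_identical(lib$h_fame - lib$h_nonexch_acid, lib$h_methyl_added)
  fa_rows <- lib[lib$class == "fatty_acid", ]
  recomputed <- vapply(fa_rows$compound,
                       function(x) hydrogen_inventory(x)$h_fame, integer(1))
  expect_identical(unname(recomputed), fa_rows$h_fame)
})
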