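# quantitation, retention indexing, correlation screen, model comparison,
# primer inference

test_that("quantitation scales by the internal standard and normalizes", {
  pk <- data.frame(compound = c("n-C16:0", "n-C18:0", "n-C24:0"),
                   area = c(500, 500, 1000))
  q <- quantify(pk, known_amount = 2)
  expect_equal(q$percent, c(50, 50))
  expect_equal(q$amount, c(1, 1))  # area == IS area -> amount == known

  tri <- data.frame(compound = c("a", "b", "c", "n-C24:0"),
                    area = c(200, 100, 100, 400))
  expect_equal(quantify(tri)$percent, c(50, 25, 25))

  # invariant to uniform area scaling
  tri2 <- tri; tri2$area <- tri2$area * 17.3
  expect_equal(quantify(tri2)$percent, quantify(tri)$percent,
               tolerance = 1e-12)
  expect_error(quantify(data.frame(compound = "a", area = 1)),
               "internal standard")
})

test_that("profile summaries report branched fraction and anteiso/iso ratio", {
  pk <- data.frame(compound = c("i-C15:0", "a-C17:0", "n-C16:0", "n-C24:0"),
                   area = c(2, 3, 5, 10))
  q <- quantify(pk)
  expect_equal(sum(q$percent), 100, tolerance = 1e-9)
  expect_equal(attr(q, "branched_fraction"), 50, tolerance = 1e-9)
  expect_equal(attr(q, "anteiso_iso_ratio"), 3 / 2, tolerance = 1e-9)
})

test_that("Kovats indices interpolate linearly and hit the rungs exactly", {
  ladder <- data.frame(carbon = 14:18, rt_min = c(10, 12, 14.5, 17, 19.2))
  expect_equal(kovats_ri(14.5, ladder), 1600)
  expect_equal(kovats_ri(15.75, ladder), 1650)
  expect_equal(kovats_ri(11.5, data.frame(carbon = c(14, 15),
                                          rt_min = c(10, 12))), 1475)
  # strictly increasing in rt
  rts <- seq(10, 19.2, length.out = 40)
  expect_true(all(diff(kovats_ri(rts, ladder)) > 0))
  expect_error(kovats_ri(9, ladder), "outside")
  expect_error(kovats_ri(25, ladder), "outside")
})

test_that("the correlation screen yields a symmetric unit-diagonal matrix", {
  x <- c(1, 2, 3, 5)
  tab <- data.frame(x = x, y = -2 * x, z = c(2, 1, 4, 3), const = 1)
  expect_message(r <- correlation_screen(tab), "zero-variance")
  expect_equal(dim(r), c(3, 3))
  expect_equal(diag(r), setNames(rep(1, 3), c("x", "y", "z")))
  expect_equal(r, t(r))
  expect_equal(r["x", "y"], -1, tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  # hand-computed Pearson r for the 4-row fixture
  expect_equal(r["x", "z"], cov(x, tab$z) / (sd(x) * sd(tab$z)),
               tolerance = 1e-12)
  expect_error(correlation_screen(tab[1:2, ]), "3 rows")
})

test_that("model comparison identifies each generator on its own data", {
  mu <- seq(0.007, 0.172, length.out = 15)

  lin <- fit_rate_eps_models(mu, -170 + 600 * mu)
  expect_lt(lin$fits$linear$rss, 1e-12)
  expect_equal(lin$ranking[1], "linear")

  # exponential decay truth with small noise: parameters within 10%
  set.seed(7)
  eps_exp <- -60 - 120 * exp(-10 * mu) + rnorm(15, 0, 0.5)
  fe <- fit_rate_eps_models(mu, eps_exp)
  pe <- fe$fits$exponential_decay$params
  expect_equal(unname(pe["k"]), 10, tolerance = 0.1)
  expect_equal(unname(pe["cc"]), -120, tolerance = 0.1)
  expect_equal(unname(pe["e_inf"]), -60, tolerance = 0.1)

  hyp <- fit_rate_eps_models(mu, -40 - 3 / (0.02 + mu))
  expect_equal(hyp$ranking[1], "hyperbolic")
  expect_lt(hyp$fits$hyperbolic$rss, 1e-6)

  # a study-like span: all three models fit and a ranking is reported
  set.seed(21)
  eps_study <- -171 + (mu - 0.007) / (0.172 - 0.007) * 112 + rnorm(15, 0, 8)
  fs <- fit_rate_eps_models(mu, eps_study)
  expect_true(all(vapply(fs$fits, `[[`, logical(1), "converged")))
  expect_length(fs$ranking, 3)
  expect_true(is.logical(fs$indistinguishable))
  expect_error(fit_rate_eps_models(mu[1:4], eps_study[1:4]), "at least 5")
})

test_that("primer mass balance reproduces its arithmetic and identities", {
  inv <- hydrogen_inventory("a-C17:0")
  # fame basis: 9 of 36 H, exactly 25%
  pf <- primer_mass_balance(-200, -170, inv, -55, basis = "fame")
  expect_equal(pf$primer_fraction, 25)
  # free-acid basis oracle: (33*(-200) - 24*(-170)) / 9 = -280
  pa <- primer_mass_balance(-200, -170, inv, -55, basis = "free_acid")
  expect_equal(pa$delta_primer$value, -280, tolerance = 1e-9)
  expect_equal(pa$primer_fraction, 100 * 9 / 33, tolerance = 1e-9)
  # uniform pool: anteiso == elongation proxy implies primer == both
  pu <- primer_mass_balance(-200, -200, inv, -55)
  expect_equal(pu$delta_primer$value, -200, tolerance = 1e-12)
  # inverse consistency: recombining returns delta_anteiso exactly
  w <- c(9, 33 - 9)
  recomb <- (pa$delta_primer$value * w[1] + -170 * w[2]) / sum(w)
  expect_equal(recomb, -200, tolerance = 1e-12)
  expect_error(primer_mass_balance(-200, -170,
                                   polyacid_inventory(8, 6, 2), -55),
               "primer")
})
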