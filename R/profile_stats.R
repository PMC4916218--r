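# Lipid profile quantitation, Kovats retention indexing, the correlation
# screen, growth-rate vs fractionation model comparison, and the
# branched-chain primer mass-balance inference.

#' Quantify a lipid profile against an internal standard
#'
#' Amounts are peak areas scaled by the coinjected internal standard of
#' known amount (`amount_i = area_i / area_IS * known_amount`); percent
#' abundances exclude the internal standard from the total. Percentages
#' are invariant to uniform scaling of all areas.
#'
#' @param peaks data.frame with columns `compound` and `area`.
#' @param is_compound internal-standard compound label (default
#'   `"n-C24:0"`).
#' @param known_amount amount of coinjected internal standard (any unit;
#'   default 1).
#' @return object of class `profile_summary`: data.frame (`compound`,
#'   `amount`, `percent`) with attributes `branched_fraction` (percent of
#'   total in iso + anteiso acids) and `anteiso_iso_ratio`.
#' @export
quantify <- function(peaks, is_compound = "n-C24:0", known_amount = 1) {
  check_columns(peaks, c("compound", "area"), "peaks")
  is_area <- peaks$area[peaks$compound == is_compound]
  if (length(is_area) != 1 || is.na(is_area) || is_area <= 0) {
    stop(sprintf("quantify: internal standard '%s' peak missing or empty",
                 is_compound))
  }
  a <- peaks[peaks$compound != is_compound & !is.na(peaks$area), , drop = FALSE]
  if (nrow(a) == 0) stop("quantify: no analyte peaks")
  amount <- a$area / is_area * known_amount
  percent <- 100 * amount / sum(amount)
  out <- data.frame(compound = a$compound, amount = amount, percent = percent,
                    stringsAsFactors = FALSE)
  branching <- vapply(out$compound, function(x) {
    fa <- tryCatch(parse_lipid_label(x), error = function(e) NULL)
    if (is.null(fa)) NA_character_ else fa$branching
  }, character(1))
  br <- sum(out$percent[branching %in% c("iso", "anteiso")])
  ai <- sum(out$percent[branching %in% "anteiso"]) /
    sum(out$percent[branching %in% "iso"])
  structure(out, branched_fraction = br, anteiso_iso_ratio = ai,
            class = c("profile_summary", "data.frame"))
}

#' Kovats retention index by linear interpolation
#'
#' For temperature-programmed GC, the index interpolates linearly between
#' the bracketing n-alkane rungs:
#' `RI = 100 n + 100 (rt - t_n) / (t_{n+1} - t_n)`.
#'
#' @param rt retention time(s), minutes; must lie within the ladder span.
#' @param ladder data.frame with columns `carbon` (alkane carbon numbers)
#'   and `rt_min` (strictly increasing retention times).
#' @return numeric retention indices.
#' @examples
#' kovats_ri(11.5, data.frame(carbon = c(14, 15), rt_min = c(10, 12)))
#' @export
kovats_ri <- function(rt, ladder) {
  check_columns(ladder, c("carbon", "rt_min"), "alkane ladder")
  ladder <- ladder[order(ladder$carbon), , drop = FALSE]
  if (nrow(ladder) < 2) stop("kovats_ri: ladder needs at least 2 rungs")
  if (any(diff(ladder$rt_min) <= 0)) {
    stop("kovats_ri: ladder retention times must increase with carbon number")
  }
  if (any(rt < min(ladder$rt_min) | rt > max(ladder$rt_min))) {
    stop("kovats_ri: retention time outside the alkane ladder span")
  }
  vapply(rt, function(x) {
    i <- max(which(ladder$rt_min <= x))
    if (i == nrow(ladder)) i <- i - 1L
    n <- ladder$carbon[i]
    100 * n + 100 * (ladder$carbon[i + 1] - n) *
      (x - ladder$rt_min[i]) / (ladder$rt_min[i + 1] - ladder$rt_min[i])
  }, numeric(1))
}

#' Pearson correlation screen across study variables
#'
#' Computes the full symmetric Pearson correlation matrix over the numeric
#' columns of a per-cell table (abundances, growth rate, total
#' fractionation). Zero-variance columns are excluded with a message.
#'
#' @param table data.frame; non-numeric columns are dropped.
#' @param p_adjust if `TRUE`, also return Benjamini-Hochberg adjusted
#'   p-values per pair.
#' @return the correlation matrix, or (with `p_adjust`) a list with `r`
#'   and `p_adj` matrices.
#' @export
correlation_screen <- function(table, p_adjust = FALSE) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("correlation_screen: need at least 3 rows")
  v <- vapply(num, function(x) stats::var(x, na.rm = TRUE), numeric(1))
  dropped <- names(num)[!is.na(v) & v == 0]
  if (length(dropped) > 0) {
    message("correlation_screen: excluding zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    num <- num[!(names(num) %in% dropped)]
  }
  r <- stats::cor(as.matrix(num), use = "pairwise.complete.obs",
                  method = "pearson")
  if (!p_adjust) return(r)
  k <- ncol(num); n <- nrow(num)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      p[i, j] <- stats::cor.test(num[[i]], num[[j]])$p.value
    }
  }
  upper <- p[upper.tri(p)]
  p[upper.tri(p)] <- stats::p.adjust(upper, method = "BH")
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- 0
  list(r = r, p_adj = p)
}

#' Fit candidate growth-rate vs fractionation models
#'
#' Fits three least-squares models of total fractionation against growth
#' rate -- linear `eps = a + b mu`, exponential decay
#' `eps = eps_inf + c exp(-k mu)`, and hyperbolic
#' `eps = eps_inf + c / (K + mu)` -- and ranks them by AICc. When the top
#' two models differ by less than 2 AICc units the ranking is reported as
#' indistinguishable. A model that fails to converge is flagged and the
#' others are returned.
#'
#' @param mu growth rates (1/h), length >= 5.
#' @param eps total fractionations (permil).
#' @return object of class `rate_eps_fits`: list of per-model fits
#'   (`params`, `rss`, `aicc`, `converged`, `predict`), plus `ranking`,
#'   `best` and `indistinguishable`.
#' @export
fit_rate_eps_models <- function(mu, eps) {
  stopifnot(length(mu) == length(eps))
  ok <- !is.na(mu) & !is.na(eps)
  mu <- mu[ok]; eps <- eps[ok]
  n <- length(mu)
  if (n < 5) stop("fit_rate_eps_models: need at least 5 (mu, eps) pairs")

  aicc <- function(rss, p) {
    k <- p + 1  # + residual variance
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  fits <- list()

  lin <- stats::lm(eps ~ mu)
  rss <- sum(stats::residuals(lin)^2)
  fits$linear <- list(
    model = "linear", params = stats::coef(lin),
    rss = rss, aicc = aicc(rss, 2), converged = TRUE,
    predict = local({cf <- stats::coef(lin); function(m) cf[1] + cf[2] * m}))

  nls_best <- function(form, starts) {
    best <- NULL
    for (st in starts) {
      f <- tryCatch(
        minpack.lm::nlsLM(form, data = data.frame(mu = mu, eps = eps),
                          start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(f)) next
      r <- sum(stats::residuals(f)^2)
      if (is.null(best) || r < best$rss) best <- list(fit = f, rss = r)
    }
    best
  }

  e_inf0 <- eps[which.max(mu)]
  c0 <- eps[which.min(mu)] - e_inf0
  exp_starts <- lapply(c(2, 5, 10, 20, 50), function(k0) {
    list(e_inf = e_inf0, cc = c0 * exp(k0 * min(mu)), k = k0)
  })
  b <- nls_best(eps ~ e_inf + cc * exp(-k * mu), exp_starts)
  fits$exponential_decay <- if (is.null(b)) {
    list(model = "exponential_decay", params = NULL, rss = NA_real_,
         aicc = NA_real_, converged = FALSE, predict = function(m) rep(NA_real_, length(m)))
  } else {
    cf <- stats::coef(b$fit)
    list(model = "exponential_decay", params = cf, rss = b$rss,
         aicc = aicc(b$rss, 3), converged = TRUE,
         predict = function(m) cf["e_inf"] + cf["cc"] * exp(-cf["k"] * m))
  }

  hyp_starts <- lapply(c(0.005, 0.02, 0.05, 0.2), function(K0) {
    list(e_inf = e_inf0, cc = c0 * (K0 + min(mu)), K = K0)
  })
  b <- nls_best(eps ~ e_inf + cc / (K + mu), hyp_starts)
  fits$hyperbolic <- if (is.null(b)) {
    list(model = "hyperbolic", params = NULL, rss = NA_real_,
         aicc = NA_real_, converged = FALSE, predict = function(m) rep(NA_real_, length(m)))
  } else {
    cf <- stats::coef(b$fit)
    list(model = "hyperbolic", params = cf, rss = b$rss,
         aicc = aicc(b$rss, 3), converged = TRUE,
         predict = function(m) cf["e_inf"] + cf["cc"] / (cf["K"] + m))
  }

  a <- vapply(fits, `[[`, numeric(1), "aicc")
  ranking <- names(sort(a, na.last = TRUE))
  conv <- ranking[!is.na(a[ranking])]
  indist <- length(conv) >= 2 && (a[conv[2]] - a[conv[1]]) < 2
  structure(
    list(fits = fits, n = n, ranking = ranking,
         best = if (indist) NA_character_ else conv[1],
         indistinguishable = indist),
    class = "rate_eps_fits"
  )
}

#' @export
print.rate_eps_fits <- function(x, ...) {
  cat(sprintf("<rate_eps_fits> n = %d pairs\n", x$n))
  for (nm in x$ranking) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (f$converged) sprintf("rss %.4g, AICc %.2f", f$rss, f$aicc)
                else "did not converge"))
  }
  cat(if (x$indistinguishable) {
    "  top models indistinguishable (delta AICc < 2)\n"
  } else sprintf("  best by AICc: %s\n", x$best))
  invisible(x)
}

#' @export
summary.rate_eps_fits <- function(object, ...) {
  do.call(rbind, lapply(object$fits, function(f) {
    data.frame(model = f$model, rss = f$rss, aicc = f$aicc,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}

#' Branched-chain primer mass-balance inference
#'
#' Treats an anteiso fatty acid's non-exchangeable hydrogen as a two-pool
#' mixture of primer-derived hydrogen (9 atoms for the isoleucine-derived
#' 2-methylbutyryl primer) and elongation-derived hydrogen (proxied by a
#' measured straight-chain homolog), and solves for the primer's delta:
#' `d_primer = (n_tot d_anteiso - (n_tot - h_primer) d_elong) / h_primer`.
#' The denominator `n_tot` is the free acid's non-exchangeable count
#' (default basis) or the methyl ester's; the primer fraction is exactly
#' 25% for anteiso-C17:0 only under the methyl-ester basis (9 of 36), so
#' both fractions are reported.
#'
#' @param delta_anteiso [delta_value] (or numeric permil) of the anteiso
#'   acid vs V-SMOW.
#' @param delta_elong delta of the straight-chain homolog (elongation
#'   proxy), same frame.
#' @param inventory [hydrogen_inventory()] of the anteiso acid (must carry
#'   `h_primer`).
#' @param delta_water medium water delta vs V-SMOW.
#' @param basis denominator convention, `"free_acid"` (default) or
#'   `"fame"`.
#' @return object of class `primer_inference`: list with `delta_primer`
#'   ([delta_value]), `eps_primer_water` (`fractionation_result`),
#'   `primer_fraction` (for the chosen basis, percent),
#'   `primer_fraction_free_acid`, `primer_fraction_fame`, `basis`.
#' @examples
#' primer_mass_balance(-200, -170, hydrogen_inventory("a-C17:0"), -60)
#' @export
primer_mass_balance <- function(delta_anteiso, delta_elong, inventory,
                                delta_water,
                                basis = c("free_acid", "fame")) {
  basis <- match.arg(basis)
  stopifnot(inherits(inventory, "hydrogen_inventory"))
  hp <- inventory$h_primer
  if (is.na(hp) || hp <= 0) {
    stop("primer_mass_balance: inventory carries no primer hydrogen")
  }
  n_tot <- switch(basis, free_acid = inventory$h_nonexch_acid,
                  fame = inventory$h_fame)
  a <- as_delta_value(delta_anteiso)
  e <- as_delta_value(delta_elong)
  fa <- permil_to_fraction(a$value); sa <- a$sem / 1000
  fe <- permil_to_fraction(e$value); se <- e$sem / 1000
  fp <- (n_tot * fa - (n_tot - hp) * fe) / hp
  sp <- sqrt((n_tot * sa)^2 + ((n_tot - hp) * se)^2) / hp
  delta_primer <- delta_value(fraction_to_permil(fp),
                              sem = fraction_to_permil(sp))
  structure(
    list(delta_primer = delta_primer,
         eps_primer_water = fractionation(delta_primer, delta_water),
         primer_fraction = 100 * hp / n_tot,
         primer_fraction_free_acid = 100 * hp / inventory$h_nonexch_acid,
         primer_fraction_fame = 100 * hp / inventory$h_fame,
         basis = basis, h_primer = hp, n_tot = n_tot),
    class = "primer_inference"
  )
}

#' @export
print.primer_inference <- function(x, ...) {
  cat(sprintf("<primer_inference> basis %s: primer = %d of %d H (%.1f%%)\n",
              x$basis, x$h_primer, x$n_tot, x$primer_fraction))
  cat(sprintf("  delta_primer = %.0f ‰; eps vs water = %.0f ‰\n",
              x$delta_primer$value, x$eps_primer_water$eps))
  invisible(x)
}

#' Profile, correlation and model statistics for a reduced study
#'
#' Combines a [reduce_study()] result with [fit_growth_curves()] output
#' into the study-level statistics: the per-cell profile table, the
#' Pearson correlation screen over abundances, growth rate and total
#' fractionation, the growth-rate vs fractionation model comparison, and
#' the anteiso-primer inference per cell (anteiso-C17:0 vs its
#' straight-chain homolog, where both were measured).
#'
#' @param reduction a `study_reduction`.
#' @param growth a data.frame from [fit_growth_curves()].
#' @param anteiso,elong_proxy compound labels for the primer inference.
#' @return list with `profiles` (wide per-cell percent table),
#'   `correlations` (matrix), `models` (`rate_eps_fits`), `primer`
#'   (data.frame per cell), `cell_table` (per-cell mu, eps_total).
#' @export
profile_stats <- function(reduction, growth, anteiso = "a-C17:0",
                          elong_proxy = "n-C17:0") {
  stopifnot(inherits(reduction, "study_reduction"))
  fr <- reduction$fractionation
  tot <- reduction$eps_total
  key <- cell_key(tot$strain, tot$donor, tot$sulfate_mM)
  gkey <- cell_key(growth$strain, growth$donor, growth$sulfate_mM)
  tot$mu_avg <- growth$mu_avg[match(key, gkey)]

  comps <- sort(unique(fr$compound))
  prof <- do.call(rbind, lapply(seq_len(nrow(tot)), function(i) {
    sel <- fr$strain == tot$strain[i] & fr$donor == tot$donor[i] &
      fr$sulfate_mM == tot$sulfate_mM[i]
    stats::setNames(fr$percent[sel][match(comps, fr$compound[sel])], comps)
  }))
  profiles <- cbind(tot[, c("strain", "donor", "sulfate_mM")],
                    as.data.frame(prof, check.names = FALSE))

  screen_tab <- cbind(as.data.frame(prof, check.names = FALSE),
                      mu_avg = tot$mu_avg, eps_total = tot$eps_total)
  correlations <- suppressMessages(correlation_screen(screen_tab))

  models <- if (sum(!is.na(tot$mu_avg)) >= 5) {
    fit_rate_eps_models(tot$mu_avg, tot$eps_total)
  } else NULL

  inv <- hydrogen_inventory(anteiso)
  primer <- do.call(rbind, lapply(seq_len(nrow(tot)), function(i) {
    sel <- fr$strain == tot$strain[i] & fr$donor == tot$donor[i] &
      fr$sulfate_mM == tot$sulfate_mM[i]
    da <- fr$delta_vsmow[sel][match(anteiso, fr$compound[sel])]
    de <- fr$delta_vsmow[sel][match(elong_proxy, fr$compound[sel])]
    if (is.na(da) || is.na(de)) return(NULL)
    pi_ <- primer_mass_balance(da, de, inv, fr$water_delta_permil[sel][1])
    data.frame(strain = tot$strain[i], donor = tot$donor[i],
               sulfate_mM = tot$sulfate_mM[i],
               delta_primer = pi_$delta_primer$value,
               eps_primer_water = pi_$eps_primer_water$eps,
               primer_fraction_free_acid = pi_$primer_fraction_free_acid,
               primer_fraction_fame = pi_$primer_fraction_fame,
               stringsAsFactors = FALSE)
  }))

  list(profiles = profiles, correlations = correlations, models = models,
       primer = primer,
       cell_table = tot[, c("strain", "donor", "sulfate_mM", "mu_avg",
                            "eps_total", "eps_total_sem")])
}
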