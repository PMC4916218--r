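# Modified-logistic growth curve fitting, diauxic phase detection, and
# biomass-weighted average growth rates.
#
# The growth model is the reparameterized logistic
#   OD(t) = OD0 + A / (1 + exp(4 mu (lambda - t) / A + 2))
# with asymptotic rise A, maximum slope mu attained at the inflection, and
# lag time lambda (the intercept of the inflection tangent with the
# baseline).

#' Evaluate the modified logistic growth curve
#'
#' @param t time (h).
#' @param A asymptotic OD rise above baseline.
#' @param mu maximum growth rate (slope at the inflection).
#' @param lambda lag time (h).
#' @param od0 baseline OD (default 0).
#' @return OD values.
#' @export
logistic_od <- function(t, A, mu, lambda, od0 = 0) {
  od0 + A / (1 + exp(4 * mu * (lambda - t) / A + 2))
}

#' Fit the modified logistic to one growth curve
#'
#' Least-squares fit by Levenberg-Marquardt with multiple jittered starts.
#' Starting values: `A` from the OD range, `mu` from the maximum
#' finite-difference slope, `lambda` from the inflection tangent's
#' intercept with the baseline; each start is jittered by factors 0.5-2.
#'
#' @param times numeric vector of times (h), strictly increasing.
#' @param od numeric vector of OD600 values (>= 0), same length.
#' @param n_starts number of jittered multi-starts (default 5).
#' @return object of class `logistic_fit`: list with `coefficients`
#'   (named: `A`, `mu`, `lambda`, `od0`), `rss`, `fitted`, `times`, `od`,
#'   `converged`.
#' @examples
#' t <- seq(0, 40, 0.5)
#' fit <- fit_logistic(t, logistic_od(t, A = 0.8, mu = 0.154, lambda = 5,
#'                                    od0 = 0.01))
#' coef(fit)["mu"]
#' @export
fit_logistic <- function(times, od, n_starts = 5) {
  stopifnot(length(times) == length(od))
  if (length(times) < 5) stop("fit_logistic: need at least 5 points")
  if (any(diff(times) <= 0)) stop("fit_logistic: times must be strictly increasing")
  if (any(od < 0)) stop("fit_logistic: OD must be >= 0")
  rng <- max(od) - min(od)
  if (rng <= 1e-9 || stats::sd(od) < 1e-12) {
    stop("fit_logistic: flat curve, no growth signal to fit")
  }

  # starts from the data
  A0 <- rng
  od0_0 <- min(od)
  slopes <- diff(od) / diff(times)
  i_max <- which.max(slopes)
  mu0 <- max(slopes[i_max], rng / diff(range(times)))
  t_inf <- (times[i_max] + times[i_max + 1]) / 2
  od_inf <- (od[i_max] + od[i_max + 1]) / 2
  lam0 <- t_inf - (od_inf - od0_0) / mu0
  lam0 <- max(lam0, min(times))

  jitter_sets <- list(c(1, 1, 1), c(0.5, 0.5, 1), c(2, 2, 1),
                      c(1, 0.5, 0.8), c(1, 2, 1.2), c(0.7, 1.5, 1))
  best <- NULL
  for (j in jitter_sets[seq_len(min(n_starts + 1, length(jitter_sets)))]) {
    start <- list(A = A0 * j[1], mu = mu0 * j[2],
                  lambda = lam0 * j[3], od0 = od0_0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        od ~ od0 + A / (1 + exp(4 * mu * (lambda - times) / A + 2)),
        data = data.frame(times = times, od = od),
        start = start,
        lower = c(A = 1e-8, mu = 1e-8, lambda = -Inf, od0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("fit_logistic: no start converged after multi-start")
  }
  cf <- stats::coef(best$fit)
  structure(
    list(coefficients = cf, rss = best$rss,
         fitted = as.numeric(stats::fitted(best$fit)),
         times = times, od = od, converged = TRUE),
    class = "logistic_fit"
  )
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
print.logistic_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<logistic_fit> A = %.3f, mu = %.4f /h, lambda = %.2f h, OD0 = %.3f (rss %.3g)\n",
              cf["A"], cf["mu"], cf["lambda"], cf["od0"], x$rss))
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else {
    if (is.data.frame(newdata)) newdata$times else newdata
  }
  cf <- object$coefficients
  logistic_od(t, cf["A"], cf["mu"], cf["lambda"], cf["od0"])
}

#' @export
residuals.logistic_fit <- function(object, ...) object$od - object$fitted

#' Detect mono- or diauxic growth phases
#'
#' Works on the derivative of the smoothed OD series (3-point running
#' median then 3-point mean). A second phase is declared when the
#' derivative falls below 10% of its running maximum (after a substantive
#' first phase) and later rebounds above 25% of that maximum; the series
#' is split at the intervening derivative minimum. The OD derivative (not
#' the log-OD derivative) is used because a second phase starting from a
#' high OD baseline has a small specific rate even when its absolute
#' biomass production is large. A two-phase curve with no plateau between
#' phases is reported as a single window (a stated limitation of this
#' detector).
#'
#' @param times,od the growth curve.
#' @return list of index windows (`c(start, end)` into `times`); length 1
#'   or 2.
#' @export
detect_phases <- function(times, od) {
  n <- length(times)
  single <- list(c(1L, n))
  if (n < 8) return(single)
  sm <- stats::runmed(od, k = 3, endrule = "median")
  sm <- as.numeric(stats::filter(sm, rep(1 / 3, 3), sides = 2))
  sm[1] <- od[1]; sm[n] <- od[n]
  d <- diff(sm) / diff(times)
  d[d < 0] <- 0
  runmax <- cummax(d)
  # only consider a slowdown after a substantive first phase, so noise in
  # the lag (where the running maximum is still tiny) cannot trigger a
  # split; like the rebound below, the dip must hold for 2 points so a
  # lone downward noise spike mid-exponential is ignored
  is_low <- d < 0.1 * runmax & runmax > 0.2 * max(d)
  low <- which(is_low & c(is_low[-1], FALSE))
  if (length(low) == 0) return(single)
  i <- low[1]
  # a real second phase sustains the rebound; a lone noise spike does not
  above <- d > 0.25 * runmax[i]
  rebound <- which(above & c(above[-1], FALSE))
  rebound <- rebound[rebound > i]
  if (length(rebound) == 0) return(single)
  j <- rebound[1]
  split <- i - 1 + which.min(d[i:j])
  # split index on the time grid (derivative index k spans points k, k+1)
  s <- split + 1L
  if (s < 5 || n - s < 4) return(single)
  list(c(1L, s), c(s, n))
}

#' Biomass-weighted average growth rate
#'
#' For diauxic growth, each phase's rate is weighted by the biomass (OD
#' rise) produced during that phase:
#' `mu_avg = sum(mu_k * dOD_k) / sum(dOD_k)`.
#'
#' @param fits data.frame with columns `mu` and `delta_od` (one row per
#'   phase), or a list of `logistic_fit` objects (then `delta_od` is each
#'   fit's asymptote `A`).
#' @return `mu_avg` (1/h).
#' @examples
#' weighted_growth_rate(data.frame(mu = c(0.10, 0.02),
#'                                 delta_od = c(0.3, 0.1)))  # 0.08
#' @export
weighted_growth_rate <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      mu = vapply(fits, function(f) unname(coef(f)["mu"]), numeric(1)),
      delta_od = vapply(fits, function(f) unname(coef(f)["A"]), numeric(1)))
  }
  check_columns(fits, c("mu", "delta_od"), "phase fits")
  use <- fits[fits$delta_od > 0, , drop = FALSE]
  if (nrow(use) == 0) {
    stop("weighted_growth_rate: no phase produced biomass (delta_od > 0)")
  }
  sum(use$mu * use$delta_od) / sum(use$delta_od)
}

#' Fit one growth curve with phase detection
#'
#' Detects growth phases, fits the modified logistic within each window,
#' and combines phase rates into the biomass-weighted average; the
#' per-phase biomass is the fitted asymptote rise `A` (noise-robust, as
#' opposed to the raw endpoint difference).
#'
#' @param times,od the growth curve (>= 5 points, times strictly
#'   increasing).
#' @return object of class `growth_fit`: list with `phases` (data.frame:
#'   `A`, `mu`, `lambda`, `od0`, `t_start`, `t_end`, `delta_od`, `rss`),
#'   `mu_avg`, `diauxic`, `fits` (the per-phase `logistic_fit`s).
#' @export
fit_growth <- function(times, od) {
  o <- order(times)
  times <- times[o]; od <- od[o]
  windows <- detect_phases(times, od)
  fits <- list()
  for (w in windows) {
    idx <- seq(w[1], w[2])
    f <- tryCatch(fit_logistic(times[idx], od[idx]), error = function(e) NULL)
    if (!is.null(f)) {
      f$window <- c(times[w[1]], times[w[2]])
      fits[[length(fits) + 1]] <- f
    }
  }
  # a split whose second phase contributes negligible biomass (< 10% of the
  # total OD rise) is a detector artifact, not diauxie: refit as one phase
  if (length(fits) == 2) {
    rises <- vapply(fits, function(f) {
      unname(predict(f, f$window[2]) - predict(f, f$window[1]))
    }, numeric(1))
    if (min(rises) < 0.1 * (max(od) - min(od))) fits <- list()
  }
  if (length(fits) == 0) {
    # fall back to a single-window fit (propagates its error if truly unfittable)
    f <- fit_logistic(times, od)
    f$window <- range(times)
    fits <- list(f)
  }
  phases <- do.call(rbind, lapply(fits, function(f) {
    cf <- coef(f)
    # biomass produced during the interval: rise of the fitted curve
    # across the window (equals ~A when the whole phase sits inside it)
    rise <- unname(predict(f, f$window[2]) - predict(f, f$window[1]))
    data.frame(A = unname(cf["A"]), mu = unname(cf["mu"]),
               lambda = unname(cf["lambda"]), od0 = unname(cf["od0"]),
               t_start = f$window[1], t_end = f$window[2],
               delta_od = rise, rss = f$rss)
  }))
  structure(
    list(phases = phases, mu_avg = weighted_growth_rate(phases),
         diauxic = nrow(phases) > 1, fits = fits,
         times = times, od = od),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s, mu_avg = %.4f /h\n",
              if (x$diauxic) "diauxic (2 phases)" else "monophasic", x$mu_avg))
  print(round(x$phases, 4))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu_avg = object$mu_avg,
    stats::setNames(object$phases$mu, paste0("mu", seq_len(nrow(object$phases)))))
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else {
    if (is.data.frame(newdata)) newdata$times else newdata
  }
  out <- rep(NA_real_, length(t))
  for (i in seq_along(object$fits)) {
    f <- object$fits[[i]]
    inw <- t >= f$window[1] & t <= f$window[2]
    out[inw] <- predict(f, t[inw])
  }
  out
}

#' Summarize replicate growth fits for one condition
#'
#' @param mu_values per-replicate biomass-weighted average rates.
#' @return list with `mu_avg` (mean), `mu_sem` (SEM; `NA` for a single
#'   replicate), `n`.
#' @export
replicate_growth_summary <- function(mu_values) {
  mu_values <- mu_values[!is.na(mu_values)]
  if (length(mu_values) == 0) stop("replicate_growth_summary: no replicates")
  n <- length(mu_values)
  list(mu_avg = mean(mu_values),
       mu_sem = if (n > 1) stats::sd(mu_values) / sqrt(n) else NA_real_,
       n = n)
}

#' Fit growth curves for a whole study
#'
#' Fits every (strain, donor, sulfate, biological replicate) OD series in
#' an od table and summarizes replicates per strain x condition cell.
#'
#' @param od an od data.frame or CSV path (see [read_od()]).
#' @return data.frame with one row per cell: `strain`, `donor`,
#'   `sulfate_mM`, `mu_avg`, `mu_sem`, `n_rep`, `diauxic` (TRUE if any
#'   replicate was diauxic).
#' @export
fit_growth_curves <- function(od) {
  od <- read_od(od)
  key <- interaction(od$strain, od$donor, od$sulfate_mM, od$bio_rep,
                     drop = TRUE)
  per_rep <- lapply(split(od, key), function(d) {
    g <- fit_growth(d$time_h, d$od600)
    data.frame(strain = d$strain[1], donor = d$donor[1],
               sulfate_mM = d$sulfate_mM[1], bio_rep = d$bio_rep[1],
               mu_avg = g$mu_avg, diauxic = g$diauxic,
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, per_rep)
  cells <- unique(reps[, c("strain", "donor", "sulfate_mM")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- reps$strain == cells$strain[i] & reps$donor == cells$donor[i] &
      reps$sulfate_mM == cells$sulfate_mM[i]
    s <- replicate_growth_summary(reps$mu_avg[sel])
    data.frame(strain = cells$strain[i], donor = cells$donor[i],
               sulfate_mM = cells$sulfate_mM[i],
               mu_avg = s$mu_avg, mu_sem = s$mu_sem, n_rep = s$n,
               diauxic = any(reps$diauxic[sel]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$strain, out$donor, out$sulfate_mM), , drop = FALSE]
}
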