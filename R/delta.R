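# Delta notation, unit conversion, and the two core isotope identities
# (reference chaining and apparent fractionation). All arithmetic is done
# in fractional units; permil appears only at the interface.

#' Convert permil delta values to fractional units
#'
#' Isotope delta values are conventionally reported in permil; internally
#' all arithmetic is carried out on the dimensionless fractional deviation
#' `delta/1000`, which is what enters the ratio identities.
#'
#' @param x numeric vector of delta values in permil. Must be > -1000
#'   (a delta of -1000 permil would imply a zero isotope ratio).
#' @return numeric vector of fractional deviations.
#' @seealso [fraction_to_permil()]
#' @examples
#' permil_to_fraction(-171)   # -0.171
#' @export
permil_to_fraction <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x <= -1000, na.rm = TRUE)) {
    stop("delta values must exceed -1000 permil (isotope ratio must be positive)")
  }
  x / 1000
}

#' Convert fractional deviations back to permil
#'
#' @param x numeric vector of fractional deviations (> -1).
#' @return numeric vector in permil.
#' @export
fraction_to_permil <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x <= -1, na.rm = TRUE)) {
    stop("fractional deviations must exceed -1")
  }
  x * 1000
}

#' A delta-2H value with uncertainty
#'
#' Lightweight container for one or more hydrogen-isotope delta values
#' (permil) against a named reference frame, with a standard error of the
#' mean and a replicate count. All exported isotope operations accept and
#' return this class; bare numerics are promoted with `sem = 0`, `n = 1`.
#'
#' @param value numeric, delta in permil vs `reference`; must be > -1000.
#' @param sem numeric, standard error of the mean in permil; >= 0.
#' @param n integer replicate count; >= 1.
#' @param reference one of `"V-SMOW"`, `"coinjected-ref"`, `"media-water"`.
#' @return an object of class `delta_value`.
#' @examples
#' delta_value(-171, sem = 2.1, n = 4)
#' @export
delta_value <- function(value, sem = 0, n = 1L,
                        reference = c("V-SMOW", "coinjected-ref", "media-water")) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(value), is.numeric(sem))
  if (any(value <= -1000, na.rm = TRUE)) {
    stop("delta_value: value must exceed -1000 permil")
  }
  if (any(sem < 0, na.rm = TRUE)) stop("delta_value: sem must be >= 0")
  n <- as.integer(n)
  if (any(n < 1, na.rm = TRUE)) stop("delta_value: n must be >= 1")
  len <- max(length(value), length(sem), length(n))
  structure(
    list(value = rep_len(value, len), sem = rep_len(sem, len),
         n = rep_len(n, len), reference = reference),
    class = "delta_value"
  )
}

#' @export
print.delta_value <- function(x, digits = 2, ...) {
  cat(sprintf("<delta_value vs %s>\n", x$reference))
  cat(paste0(
    "  ", format(round(x$value, digits)), " ‰ (sem ",
    format(round(x$sem, digits)), ", n = ", x$n, ")",
    collapse = "\n"
  ), "\n")
  invisible(x)
}

#' @export
as.data.frame.delta_value <- function(x, ...) {
  data.frame(value = x$value, sem = x$sem, n = x$n,
             reference = x$reference, stringsAsFactors = FALSE)
}

# promote numerics (permil) to delta_value
as_delta_value <- function(x, reference = "V-SMOW") {
  if (inherits(x, "delta_value")) return(x)
  delta_value(x, sem = 0, n = 1L, reference = reference)
}

#' Re-reference a delta value measured against a coinjected standard
#'
#' Chains a delta measured against a working reference (e.g. coinjected
#' methyl tetracosanoate) onto the V-SMOW scale through the reference's
#' known composition: in fractional units,
#' `d_s/VSMOW = (1 + d_s/ref) * (1 + d_ref/VSMOW) - 1`.
#' Standard errors are propagated to first order.
#'
#' @param delta_sample_vs_ref [delta_value] (or numeric permil) vs the
#'   coinjected reference.
#' @param delta_ref_vsmow [delta_value] (or numeric permil): the reference's
#'   known delta vs V-SMOW.
#' @return a [delta_value] vs V-SMOW.
#' @examples
#' reference_to_vsmow(-100, -50)  # -145 permil
#' @export
reference_to_vsmow <- function(delta_sample_vs_ref, delta_ref_vsmow) {
  s <- as_delta_value(delta_sample_vs_ref, "coinjected-ref")
  r <- as_delta_value(delta_ref_vsmow, "V-SMOW")
  fs <- permil_to_fraction(s$value); fr <- permil_to_fraction(r$value)
  ss <- s$sem / 1000;                sr <- r$sem / 1000
  f  <- (1 + fs) * (1 + fr) - 1
  se <- sqrt(((1 + fr) * ss)^2 + ((1 + fs) * sr)^2)
  delta_value(fraction_to_permil(f), sem = fraction_to_permil(se),
              n = s$n, reference = "V-SMOW")
}

#' Invert the reference chaining
#'
#' Recovers the delta vs the coinjected reference from a V-SMOW value;
#' exact inverse of [reference_to_vsmow()].
#'
#' @inheritParams reference_to_vsmow
#' @param delta_sample_vsmow [delta_value] (or numeric permil) vs V-SMOW.
#' @return a [delta_value] vs the coinjected reference.
#' @export
vsmow_to_reference <- function(delta_sample_vsmow, delta_ref_vsmow) {
  s <- as_delta_value(delta_sample_vsmow, "V-SMOW")
  r <- as_delta_value(delta_ref_vsmow, "V-SMOW")
  fs <- permil_to_fraction(s$value); fr <- permil_to_fraction(r$value)
  ss <- s$sem / 1000
  f  <- (1 + fs) / (1 + fr) - 1
  se <- ss / (1 + fr)
  delta_value(fraction_to_permil(f), sem = fraction_to_permil(se),
              n = s$n, reference = "coinjected-ref")
}

#' Apparent lipid-water hydrogen isotope fractionation
#'
#' Computes the apparent fractionation between a lipid and the growth
#' medium water, `eps = alpha - 1` with
#' `alpha = (delta_lipid + 1) / (delta_water + 1)` (fractional units),
#' reported in permil. Standard errors are propagated to first order.
#'
#' @param delta_lipid [delta_value] (or numeric permil) of the lipid vs
#'   V-SMOW.
#' @param delta_water [delta_value] (or numeric permil) of the medium water
#'   vs V-SMOW.
#' @return object of class `fractionation_result`: a list with `eps`
#'   (permil), `sem`, `alpha`, `delta_lipid`, `delta_water`, `n`.
#' @examples
#' fractionation(-150, 50)$eps  # -190.48 permil
#' @export
fractionation <- function(delta_lipid, delta_water) {
  l <- as_delta_value(delta_lipid, "V-SMOW")
  w <- as_delta_value(delta_water, "V-SMOW")
  fl <- permil_to_fraction(l$value); fw <- permil_to_fraction(w$value)
  sl <- l$sem / 1000;                sw <- w$sem / 1000
  alpha <- (1 + fl) / (1 + fw)
  eps <- alpha - 1
  # d eps / d fl = 1/(1+fw); d eps / d fw = -(1+fl)/(1+fw)^2
  se <- sqrt((sl / (1 + fw))^2 + ((1 + fl) * sw / (1 + fw)^2)^2)
  structure(
    list(eps = fraction_to_permil(eps), sem = fraction_to_permil(se),
         alpha = alpha, delta_lipid = l$value, delta_water = w$value,
         n = l$n),
    class = "fractionation_result"
  )
}

#' @export
print.fractionation_result <- function(x, digits = 2, ...) {
  cat("<fractionation_result>\n")
  cat(paste0("  eps = ", format(round(x$eps, digits)), " ‰ (sem ",
             format(round(x$sem, digits)), ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Aggregate pseudoreplicate injections of one analyte
#'
#' Repeated injections of the same extract (pseudoreplicates) are combined
#' as their mean; the standard error is the larger of the sample-based
#' `sd/sqrt(n)` and the instrument floor `rms_floor/sqrt(n)`, so that a
#' run of identical (or single) injections still carries the session's
#' measured instrument uncertainty.
#'
#' @param values numeric vector of delta values in permil (one per
#'   injection), or a [delta_value].
#' @param rms_floor session instrument root-mean-square error in permil
#'   (from the bracketing standards); default 5.5.
#' @param reference reference frame of the inputs.
#' @return a single-element [delta_value].
#' @examples
#' aggregate_pseudoreplicates(c(-148, -150, -152))
#' @export
aggregate_pseudoreplicates <- function(values, rms_floor = 5.5,
                                       reference = "V-SMOW") {
  if (inherits(values, "delta_value")) {
    reference <- values$reference
    values <- values$value
  }
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("aggregate_pseudoreplicates: no replicates")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) / sqrt(n) else NA_real_
  sem <- max(s, rms_floor / sqrt(n), na.rm = TRUE)
  delta_value(m, sem = sem, n = n, reference = reference)
}
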