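#' Construct a set of biomass-specific conversion rates
#'
#' Rates q are in mmol (g biomass)^-1 h^-1, signed: substrate uptake is
#' negative, product formation non-negative.
#'
#' @param q Named numeric vector of rates (names are compound names).
#' @param sd Optional named numeric vector of standard deviations.
#' @param substrate Name of the substrate (its rate must be negative).
#' @return `rate_set` data frame with columns `compound`, `q`, `sd`.
#' @export
rate_set <- function(q, sd = NULL, substrate = "galacturonate") {
  stopifnot(is.numeric(q), !is.null(names(q)))
  if (!substrate %in% names(q)) {
    stop("substrate '", substrate, "' missing from rates")
  }
  if (q[[substrate]] >= 0) {
    stop("substrate uptake rate must be negative (uptake convention)")
  }
  if (any(q[setdiff(names(q), substrate)] < 0)) {
    stop("product rates must be non-negative")
  }
  sdv <- rep(NA_real_, length(q))
  if (!is.null(sd)) sdv <- unname(sd[names(q)])
  out <- data.frame(compound = names(q), q = unname(q), sd = sdv,
                    stringsAsFactors = FALSE)
  attr(out, "substrate") <- substrate
  class(out) <- c("rate_set", "data.frame")
  out
}

#' Construct a set of product yields on substrate
#'
#' Carbon-containing products are in Cmol (Cmol substrate)^-1; H2 (and any
#' other carbon-free species) in mol (Cmol substrate)^-1, mirroring the
#' mixed units of chemostat yield tables.
#'
#' @param y Named numeric vector of yields.
#' @param sd Optional named numeric vector of standard deviations.
#' @param registry Compound registry used to assign units per species.
#' @return `yield_set` data frame with columns `compound`, `yield`, `sd`,
#'   `unit` (`"cmol_per_cmol"` or `"mol_per_cmol"`).
#' @export
yield_set <- function(y, sd = NULL, registry = default_registry()) {
  stopifnot(is.numeric(y), !is.null(names(y)))
  if (any(y < 0)) stop("yields must be non-negative")
  unknown <- setdiff(names(y), names(registry))
  if (length(unknown)) {
    stop("compounds missing from registry: ", paste(unknown, collapse = ", "))
  }
  unit <- vapply(names(y), function(nm) {
    if (registry[[nm]]$carbons > 0) "cmol_per_cmol" else "mol_per_cmol"
  }, character(1))
  if (any(y[unit == "cmol_per_cmol"] > 1)) {
    stop("a carbon yield above 1 Cmol/Cmol violates the carbon balance")
  }
  sdv <- rep(NA_real_, length(y))
  if (!is.null(sd)) sdv <- unname(sd[names(y)])
  out <- data.frame(compound = names(y), yield = unname(y), sd = sdv,
                    unit = unname(unit), stringsAsFactors = FALSE)
  class(out) <- c("yield_set", "data.frame")
  out
}

#' Derive product yields from biomass-specific conversion rates
#'
#' For a carbon product i, Y_i = q_i C_i / (|q_s| C_s) in Cmol/Cmol; for a
#' carbon-free product such as H2, Y = q / (|q_s| C_s) in mol/Cmol.
#'
#' @param rates A `rate_set`.
#' @param registry Compound registry supplying carbon counts.
#' @param substrate Substrate name; defaults to the rate set's substrate.
#' @return `yield_set` for all products in `rates`.
#' @export
yields_from_rates <- function(rates, registry = default_registry(),
                              substrate = attr(rates, "substrate")) {
  stopifnot(inherits(rates, "rate_set"))
  qs <- rates$q[rates$compound == substrate]
  if (length(qs) != 1L || qs == 0) {
    stop("substrate rate is zero or missing; cannot normalise yields")
  }
  cs <- registry[[substrate]]$carbons
  prod <- rates[rates$compound != substrate, , drop = FALSE]
  y <- vapply(seq_len(nrow(prod)), function(i) {
    cmp <- registry[[prod$compound[i]]]
    if (is.null(cmp)) stop("compound missing from registry: ", prod$compound[i])
    ci <- if (cmp$carbons > 0) cmp$carbons else 1
    prod$q[i] * ci / (abs(qs) * cs)
  }, numeric(1))
  names(y) <- prod$compound
  yield_set(y, registry = registry)
}

#' Reconstruct biomass-specific rates from yields
#'
#' Inverse of [yields_from_rates()] given the substrate uptake rate;
#' used for round-trip consistency checks.
#'
#' @param yields A `yield_set`.
#' @param q_substrate Substrate uptake rate (negative).
#' @param registry Compound registry.
#' @param substrate Substrate name.
#' @return `rate_set` including the substrate row.
#' @export
rates_from_yields <- function(yields, q_substrate,
                              registry = default_registry(),
                              substrate = "galacturonate") {
  stopifnot(inherits(yields, "yield_set"), q_substrate < 0)
  cs <- registry[[substrate]]$carbons
  q <- vapply(seq_len(nrow(yields)), function(i) {
    cmp <- registry[[yields$compound[i]]]
    ci <- if (cmp$carbons > 0) cmp$carbons else 1
    yields$yield[i] * abs(q_substrate) * cs / ci
  }, numeric(1))
  names(q) <- yields$compound
  q[substrate] <- q_substrate
  rate_set(q, substrate = substrate)
}

#' Carbon recovery of a yield set
#'
#' 100 x the sum of carbon yields (Cmol/Cmol); carbon-free species (H2)
#' are excluded. A fully closed balance gives 100%.
#'
#' @param yields A `yield_set`.
#' @return Percent carbon recovered.
#' @export
carbon_recovery <- function(yields) {
  stopifnot(inherits(yields, "yield_set"))
  100 * sum(yields$yield[yields$unit == "cmol_per_cmol"])
}

#' Electron (degree-of-reduction) recovery of a yield set
#'
#' 100 x [sum over carbon products of Y_i gamma_cmol,i + Y_H2 * 2] /
#' gamma_cmol,substrate. H2 carries 2 electron equivalents per mol.
#'
#' @param yields A `yield_set`.
#' @param registry Compound registry supplying degrees of reduction.
#' @param substrate Substrate name.
#' @return Percent of substrate electrons recovered in products.
#' @export
electron_recovery <- function(yields, registry = default_registry(),
                              substrate = "galacturonate") {
  stopifnot(inherits(yields, "yield_set"))
  missing_g <- yields$compound[
    vapply(yields$compound, function(nm) is.null(registry[[nm]]), logical(1)) &
      yields$yield != 0]
  if (length(missing_g)) {
    stop("no degree of reduction available for: ",
         paste(missing_g, collapse = ", "))
  }
  num <- sum(vapply(seq_len(nrow(yields)), function(i) {
    cmp <- registry[[yields$compound[i]]]
    if (is.null(cmp)) return(0)  # zero-yield species without gamma
    g <- if (cmp$carbons > 0) cmp$gamma_cmol else cmp$gamma_mol
    yields$yield[i] * g
  }, numeric(1)))
  100 * num / registry[[substrate]]$gamma_cmol
}

#' Acetyl-CoA derivative yield
#'
#' Acetate is the only acetyl-CoA-derived product in this culture, so the
#' molar acetyl-CoA derivative yield is the acetate carbon yield divided by
#' 2 (two carbons per acetate), in mol (Cmol substrate)^-1.
#'
#' @param yields A `yield_set` containing an `acetate` row (Cmol/Cmol).
#' @return Yield in mol acetyl-CoA derivatives per Cmol substrate.
#' @export
acetyl_coa_derivative_yield <- function(yields) {
  stopifnot(inherits(yields, "yield_set"))
  y <- yields$yield[yields$compound == "acetate"]
  if (!length(y)) return(0)
  y / 2
}

#' Round half away from zero
#'
#' Recovery percentages are reported as integers with halves rounded away
#' from zero (so 92.5 -> 93), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round far below the reporting precision so that binary artefacts
  # like 0.285 * 100 = 28.4999... still count as an exact half
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}
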