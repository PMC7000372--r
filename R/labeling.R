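# Dynamic model of 13C-bicarbonate titrant incorporation in a chemostat.
#
# When a fully labeled 1 M NaH13CO3 solution replaces NaOH as pH titrant,
# every mole of base demand delivers one mole of labeled carbon into the
# dissolved inorganic carbon (DIC) pool. Acetate made by the WLP draws its
# carbonyl (and, in the canonical variant, also its methyl) carbon from
# DIC; acetate made by direct pyruvate cleavage stays at natural
# abundance. Position-specific acetate pool enrichments then follow
# first-order chemostat washout dynamics.

#' Chemostat configuration for the labeling experiment
#'
#' @param dilution_rate Dilution rate D (h^-1).
#' @param volume Working volume (L).
#' @param biomass Biomass concentration C_x (g L^-1). Enrichment fractions
#'   are invariant to C_x (pools and fluxes scale together); it only sets
#'   absolute concentrations.
#' @param feed_substrate Feed substrate concentration (mmol L^-1).
#' @param ph Culture pH (validity range 6-9).
#' @param temperature Temperature (deg C).
#' @param titrant_conc Titrant concentration (mol L^-1).
#' @param natural_abundance Baseline 13C fraction a0 (the NMR baseline of
#'   these cultures, 0.010).
#' @param headspace_flow Headspace N2 flow (mL min^-1), informational.
#' @param k_strip First-order CO2 stripping constant (h^-1); 0 for
#'   headspace flushing without sparging.
#' @param dic0 Optional override of the pre-switch DIC pool (mmol L^-1);
#'   default C_x q_CO2 f_HCO3 / D.
#' @return `chemostat_config` list.
#' @export
chemostat_config <- function(dilution_rate = 0.1, volume = 0.5, biomass = 1,
                             feed_substrate = 25, ph = 7.8, temperature = 30,
                             titrant_conc = 1, natural_abundance = 0.010,
                             headspace_flow = 120, k_strip = 0,
                             dic0 = NULL) {
  stopifnot(dilution_rate > 0, natural_abundance >= 0,
            natural_abundance < 1, k_strip >= 0)
  if (ph < 6 || ph > 9) stop("pH ", ph, " outside supported range [6, 9]")
  structure(list(dilution_rate = dilution_rate, volume = volume,
                 biomass = biomass, feed_substrate = feed_substrate,
                 ph = ph, temperature = temperature,
                 titrant_conc = titrant_conc,
                 natural_abundance = natural_abundance,
                 headspace_flow = headspace_flow, k_strip = k_strip,
                 dic0 = dic0),
            class = "chemostat_config")
}

#' Labeling scenario
#'
#' \describe{
#'   \item{CANONICAL_WLP}{both acetate carbons of WLP acetate drawn from
#'     DIC}
#'   \item{FORMATE_METHYL}{carbonyl from DIC; methyl from intracellular
#'     PFL-derived formate at natural abundance}
#'   \item{NO_WLP}{no DIC incorporation; both positions stay at natural
#'     abundance}
#' }
#'
#' @param name Scenario name.
#' @param f_wlp Fraction of produced acetate made by the WLP (0-1).
#' @param k_exchange Optional first-order carboxyl-CO2 exchange constant
#'   (h^-1) acting on the acetate carbonyl pool; default 0.
#' @return `scenario` list.
#' @export
scenario <- function(name = c("CANONICAL_WLP", "FORMATE_METHYL", "NO_WLP"),
                     f_wlp = 0.2, k_exchange = 0) {
  name <- match.arg(name)
  stopifnot(f_wlp >= 0, f_wlp <= 1, k_exchange >= 0)
  if (name == "NO_WLP") f_wlp <- 0
  structure(list(name = name, f_wlp = f_wlp, k_exchange = k_exchange),
            class = "scenario")
}

#' Bicarbonate fraction of dissolved inorganic carbon
#'
#' Henderson-Hasselbalch with pKa1 = 6.35 (carbonic acid/bicarbonate at
#' 30 deg C); carbonate is neglected below pH 9.
#'
#' @param ph Culture pH.
#' @param temperature Temperature (deg C), currently informational.
#' @return Fraction of DIC present as HCO3-.
#' @export
dic_speciation <- function(ph, temperature = 30) {
  1 / (1 + 10^(6.35 - ph))
}

#' Labeled DIC input rate from pH titration
#'
#' Base demand per liter per hour is C_x (q_ac + q_for + q_CO2 f_HCO3):
#' each acid is fully dissociated at culture pH and each retained CO2
#' consumes one base equivalent on hydration to bicarbonate. With a fully
#' labeled bicarbonate titrant the labeled DIC input rate equals the base
#' demand. H2 production consumes no base.
#'
#' @param rates A `rate_set` with acetate, formate and co2 rows.
#' @param cfg A `chemostat_config`.
#' @return Labeled DIC input rate (mmol L^-1 h^-1).
#' @export
titrant_dic_input <- function(rates, cfg) {
  q <- stats::setNames(rates$q, rates$compound)
  get0q <- function(nm) if (nm %in% names(q)) q[[nm]] else 0
  f <- dic_speciation(cfg$ph, cfg$temperature)
  demand <- cfg$biomass * (get0q("acetate") + get0q("formate") +
                           get0q("co2") * f)
  if (demand < 0) {
    stop("negative base demand; check the sign convention of the rates")
  }
  demand
}

.label_derivs <- function(t, y, p) {
  dic <- y[["dic"]]; ldic <- y[["ldic"]]
  e_me <- y[["e_me"]]; e_co <- y[["e_co"]]
  if (!all(is.finite(y))) stop("non-finite state at t = ", t)
  if (dic <= 0) stop("DIC pool went non-positive at t = ", t)
  e <- ldic / dic
  # gross CO2 production = measured net evolution + WLP uptake from DIC
  d_dic  <- p$t_in + p$r_gross - p$uptake - (p$D + p$k_strip) * dic
  d_ldic <- p$t_in * 1 + p$r_gross * p$a0 - p$uptake * e -
    (p$D + p$k_strip) * ldic
  e_new_me <- if (p$methyl_from_dic) p$f * e + (1 - p$f) * p$a0 else p$a0
  e_new_co <- p$f * e + (1 - p$f) * p$a0
  turn <- p$r_ac / p$ac  # acetate pool turnover = D at steady state
  d_e_me <- turn * (e_new_me - e_me)
  d_e_co <- turn * (e_new_co - e_co) + p$k_ex * (e - e_co)
  # carbonyl-CO2 exchange swaps carbon with DIC without net transfer
  d_ldic <- d_ldic - p$k_ex * p$ac * (e - e_co)
  d_prod <- p$r_ac
  excess <- max(e - p$a0, 0)
  d_lab <- p$r_ac * p$f * min(p$n_dic_pos * excess, 1)
  # above-background label leaving in the effluent (and stripped DIC)
  d_out <- p$D * ((ldic - p$a0 * dic) +
                  p$ac * ((e_me - p$a0) + (e_co - p$a0))) +
    p$k_strip * (ldic - p$a0 * dic)
  list(c(d_dic, d_ldic, d_e_me, d_e_co, d_prod, d_lab, d_out))
}

#' Simulate 13C-bicarbonate labeling dynamics
#'
#' Integrates the DIC and acetate position-enrichment balances from the
#' titrant switch at t = 0, starting from the pre-switch steady state with
#' all pools at natural abundance. Gross CO2 production is the measured
#' net evolution plus the WLP's DIC uptake, so that labeled carbon is
#' conserved exactly between the titrant input, the pools and the
#' effluent.
#'
#' @param cfg A `chemostat_config`.
#' @param rates A `rate_set` of biomass-specific conversion rates.
#' @param scn A `scenario`.
#' @param t_end End time (h).
#' @param t_step Output interval (h); the integrator (lsoda, relative
#'   tolerance 1e-8) controls its own internal step.
#' @param times Optional explicit output times overriding `t_end`/`t_step`.
#' @return `labeling_series` data frame: `time`, `dic`, `e_dic`,
#'   `acetate`, `e_me`, `e_co`, `cum_produced`, `cum_labeled`,
#'   `cum_excess_out` (all concentrations mmol L^-1, enrichments as
#'   fractions).
#' @export
simulate_labeling <- function(cfg, rates, scn, t_end = 8, t_step = 0.05,
                              times = NULL) {
  stopifnot(inherits(cfg, "chemostat_config"), inherits(scn, "scenario"))
  q <- stats::setNames(rates$q, rates$compound)
  a0 <- cfg$natural_abundance
  D <- cfg$dilution_rate
  f_hco3 <- dic_speciation(cfg$ph, cfg$temperature)
  r_ac <- cfg$biomass * q[["acetate"]]
  r_co2 <- cfg$biomass * q[["co2"]]
  n_dic_pos <- switch(scn$name, CANONICAL_WLP = 2, FORMATE_METHYL = 1,
                      NO_WLP = 0)
  uptake <- n_dic_pos * scn$f_wlp * r_ac
  p <- list(
    t_in = titrant_dic_input(rates, cfg),
    r_gross = r_co2 + uptake, uptake = uptake,
    D = D, k_strip = cfg$k_strip, a0 = a0,
    r_ac = r_ac, ac = cfg$biomass * q[["acetate"]] / D,
    f = scn$f_wlp, k_ex = scn$k_exchange,
    methyl_from_dic = scn$name == "CANONICAL_WLP",
    n_dic_pos = n_dic_pos)
  dic0 <- if (!is.null(cfg$dic0)) cfg$dic0 else r_co2 * f_hco3 / D
  y0 <- c(dic = dic0, ldic = a0 * dic0, e_me = a0, e_co = a0,
          cum_produced = 0, cum_labeled = 0, cum_excess_out = 0)
  if (is.null(times)) times <- seq(0, t_end, by = t_step)
  out <- deSolve::lsoda(y0, times, .label_derivs, p,
                        rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(out)
  res <- data.frame(
    time = out$time, dic = out$dic, e_dic = out$ldic / out$dic,
    acetate = p$ac, e_me = out$e_me, e_co = out$e_co,
    cum_produced = out$cum_produced, cum_labeled = out$cum_labeled,
    cum_excess_out = out$cum_excess_out)
  attr(res, "params") <- p
  attr(res, "config") <- cfg
  attr(res, "scenario") <- scn
  class(res) <- c("labeling_series", "data.frame")
  res
}

.series_at <- function(series, col, t) {
  if (t < min(series$time) - 1e-9 || t > max(series$time) + 1e-9) {
    stop("time ", t, " h outside the simulated range [",
         min(series$time), ", ", max(series$time), "]")
  }
  stats::approx(series$time, series[[col]], xout = t, rule = 2)$y
}

#' Fraction of acetate produced since the switch that carries label
#'
#' A produced molecule counts as labeled when it carries at least one 13C
#' above natural abundance: probability f_wlp x (sum of DIC-derived
#' position excess enrichments, capped at 1).
#'
#' @param series A `labeling_series`.
#' @param t Time (h) after the titrant switch; must be > 0 and covered.
#' @return Percent of acetate produced in (0, t] that is labeled.
#' @export
produced_label_fraction <- function(series, t) {
  if (t <= 0) stop("t must be after the titrant switch (t > 0)")
  prod <- .series_at(series, "cum_produced", t)
  lab <- .series_at(series, "cum_labeled", t)
  100 * lab / prod
}

#' Position-specific enrichment of the total-culture acetate pool
#'
#' Pre-switch acetate still in the reactor contributes at natural
#' abundance with weight exp(-D t) (chemostat washout); this is implicit
#' in the pool balance.
#'
#' @param series A `labeling_series`.
#' @param t Time (h).
#' @return Named vector: percent 13C in `methyl` and `carbonyl` positions.
#' @export
pool_position_enrichment <- function(series, t) {
  c(methyl = 100 * .series_at(series, "e_me", t),
    carbonyl = 100 * .series_at(series, "e_co", t))
}
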