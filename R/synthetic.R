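# Synthetic chemostat campaigns with known ground truth. The generator
# forward-simulates the labeling model under stated truth parameters and
# overlays the measurement noise of the three data streams: pseudo-steady
# state rate measurements (multiplicative log-normal; chemostat rates are
# positive and relative-error dominated), NMR position enrichments
# (additive Gaussian, truncated to [0, 100] percent) and the off-gas
# 13CO2 fraction (additive Gaussian, truncated to [0, 1]).

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth parameters for a synthetic campaign
#'
#' @param scenario_name Labeling scenario generating the data.
#' @param f_wlp True WLP share of acetate production.
#' @param cfg A `chemostat_config`.
#' @param rates True `rate_set`.
#' @param sigma_rate Multiplicative (log-normal sdlog) noise on rates.
#' @param sigma_nmr Additive noise on NMR enrichments (percentage points).
#' @param sigma_gas Additive noise on the off-gas 13CO2 fraction.
#' @param seed Integer random seed, recorded in the output.
#' @return `truth_parameters` list.
#' @export
truth_parameters <- function(scenario_name = "FORMATE_METHYL", f_wlp = 0.2,
                             cfg = chemostat_config(),
                             rates = chemostat_rates(),
                             sigma_rate = 0.05, sigma_nmr = 0.3,
                             sigma_gas = 0.005, seed = 1L) {
  stopifnot(sigma_rate >= 0, sigma_nmr >= 0, sigma_gas >= 0)
  structure(list(scenario = scenario(scenario_name, f_wlp = f_wlp),
                 cfg = cfg, rates = rates, sigma_rate = sigma_rate,
                 sigma_nmr = sigma_nmr, sigma_gas = sigma_gas,
                 seed = as.integer(seed)),
            class = "truth_parameters")
}

#' Generate a synthetic chemostat labeling campaign
#'
#' Forward-simulates the labeling model under the truth parameters and
#' samples the three observation streams. Regeneration with the same seed
#' is byte-identical.
#'
#' @param truth A `truth_parameters` object.
#' @param nmr_times NMR sampling times (h); the reference campaign
#'   reports 0, 4 and 8 h.
#' @param gas_times Off-gas sampling grid (h).
#' @param n_rate_replicates Number of noisy rate-measurement replicates.
#' @param dir Optional directory; when given, the tables are written as
#'   TSV plus a `truth.json` record.
#' @return `synthetic_campaign` list: `rates` (replicate table), `nmr`
#'   (an `nmr_observations`), `offgas`, `truth`.
#' @export
generate_campaign <- function(truth, nmr_times = c(0, 4, 8),
                              gas_times = seq(0, 8, by = 0.5),
                              n_rate_replicates = 3, dir = NULL) {
  stopifnot(inherits(truth, "truth_parameters"))
  sim_times <- sort(unique(c(0, nmr_times, gas_times)))
  series <- simulate_labeling(truth$cfg, truth$rates, truth$scenario,
                              times = sim_times)
  .with_seed(truth$seed, {
    q <- stats::setNames(truth$rates$q, truth$rates$compound)
    reps <- do.call(rbind, lapply(seq_len(n_rate_replicates), function(r) {
      noisy <- sign(q) * abs(q) *
        stats::rlnorm(length(q), meanlog = -truth$sigma_rate^2 / 2,
                      sdlog = truth$sigma_rate)
      data.frame(replicate = r, compound = names(q), q = unname(noisy))
    }))
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    nmr_true <- t(vapply(nmr_times,
                         function(t) pool_position_enrichment(series, t),
                         numeric(2)))
    nmr <- nmr_observations(
      nmr_times,
      if (truth$sigma_nmr > 0)
        clamp(nmr_true[, 1] + stats::rnorm(length(nmr_times), 0,
                                           truth$sigma_nmr), 0, 100)
      else nmr_true[, 1],
      if (truth$sigma_nmr > 0)
        clamp(nmr_true[, 2] + stats::rnorm(length(nmr_times), 0,
                                           truth$sigma_nmr), 0, 100)
      else nmr_true[, 2])
    e_gas <- vapply(gas_times, function(t) .series_at(series, "e_dic", t),
                    numeric(1))
    if (truth$sigma_gas > 0) {
      e_gas <- clamp(e_gas + stats::rnorm(length(gas_times), 0,
                                          truth$sigma_gas), 0, 1)
    }
    offgas <- data.frame(
      time_h = gas_times,
      co2_mmol_l_h = truth$cfg$biomass * q[["co2"]],
      frac_13co2 = e_gas)
    out <- structure(list(rates = reps, nmr = nmr, offgas = offgas,
                          truth = truth, series = series),
                     class = "synthetic_campaign")
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_tsv(reps, file.path(dir, "rates.tsv"))
      write_tsv(as.data.frame(nmr), file.path(dir, "nmr.tsv"))
      write_tsv(offgas, file.path(dir, "offgas.tsv"))
      jsonlite::write_json(
        list(scenario = truth$scenario$name,
             f_wlp = truth$scenario$f_wlp,
             k_exchange = truth$scenario$k_exchange,
             sigma_rate = truth$sigma_rate, sigma_nmr = truth$sigma_nmr,
             sigma_gas = truth$sigma_gas, seed = truth$seed),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

#' Mean rates of a synthetic campaign's replicate table
#'
#' @param campaign A `synthetic_campaign`.
#' @return A `rate_set` of replicate-averaged rates.
#' @export
campaign_mean_rates <- function(campaign) {
  agg <- stats::aggregate(q ~ compound, campaign$rates, mean)
  # keep the truth table's compound order
  ord <- match(campaign$truth$rates$compound, agg$compound)
  rate_set(stats::setNames(agg$q[ord], agg$compound[ord]),
           substrate = attr(campaign$truth$rates, "substrate"))
}
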