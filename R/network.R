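# Stoichiometric model of the adapted Entner-Doudoroff route to pyruvate
# plus acetate formation and the Wood-Ljungdahl pathway (WLP). Redox is a
# single pooled 2-electron currency ("epair", standing in for reduced
# ferredoxin and NAD(P)H collectively); ATP is not modelled.

.network_species <- function() {
  data.frame(
    species = c("galacturonate", "pyruvate", "acetyl_coa", "acetate",
                "co2", "formate", "h2", "epair", "biomass"),
    carbons = c(6, 3, 2, 2, 1, 1, 0, 0, 1),
    # degree of reduction per mol (acetyl-CoA counted as its C2 acetyl
    # unit; biomass per Cmol, CH1.8O0.5N0.2 -> 4.2; epair = 2 electrons)
    gamma   = c(20, 10, 8, 8, 0, 2, 2, 2, 4.2),
    boundary = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Build the galacturonate + Wood-Ljungdahl reaction network
#'
#' Reactions (all fluxes non-negative, per mol):
#' \describe{
#'   \item{ED}{galacturonate -> 2 pyruvate (adapted Entner-Doudoroff route,
#'     redox-neutral overall)}
#'   \item{PFOR}{pyruvate -> acetyl-CoA + CO2 + 1 electron pair
#'     (pyruvate:ferredoxin oxidoreductase)}
#'   \item{PFL}{pyruvate -> acetyl-CoA + formate (pyruvate formate lyase)}
#'   \item{ACK}{acetyl-CoA -> acetate (phosphotransacetylase/acetate
#'     kinase)}
#'   \item{HYD}{1 electron pair -> H2 (hydrogenase)}
#'   \item{WLP_CO2}{2 CO2 + 4 electron pairs -> acetate (canonical WLP,
#'     8 electrons per acetate)}
#'   \item{WLP_FOR}{formate + CO2 + 3 electron pairs -> acetate (WLP with
#'     formate feeding the methyl branch, 6 electrons per acetate)}
#'   \item{BIOMASS}{1/6 galacturonate + 13/30 electron pair -> 1 Cmol
#'     biomass (boundary sink with degree of reduction 4.2)}
#' }
#' The scenario chooses which WLP variant is present.
#'
#' @param scenario One of `"CANONICAL_WLP"`, `"FORMATE_METHYL"`,
#'   `"NO_WLP"`.
#' @return `reaction_network`: list with stoichiometric matrix `S`
#'   (species x reactions), species table, reaction names and the scenario.
#' @export
build_network <- function(scenario = c("CANONICAL_WLP", "FORMATE_METHYL",
                                       "NO_WLP")) {
  scenario <- match.arg(scenario)
  sp <- .network_species()
  rx <- list(
    ED      = c(galacturonate = -1, pyruvate = 2),
    PFOR    = c(pyruvate = -1, acetyl_coa = 1, co2 = 1, epair = 1),
    PFL     = c(pyruvate = -1, acetyl_coa = 1, formate = 1),
    ACK     = c(acetyl_coa = -1, acetate = 1),
    HYD     = c(epair = -1, h2 = 1),
    WLP_CO2 = c(co2 = -2, epair = -4, acetate = 1),
    WLP_FOR = c(formate = -1, co2 = -1, epair = -3, acetate = 1),
    BIOMASS = c(galacturonate = -1 / 6, epair = -13 / 30, biomass = 1)
  )
  keep <- switch(scenario,
                 CANONICAL_WLP  = setdiff(names(rx), "WLP_FOR"),
                 FORMATE_METHYL = setdiff(names(rx), "WLP_CO2"),
                 NO_WLP         = setdiff(names(rx), c("WLP_CO2", "WLP_FOR")))
  rx <- rx[keep]
  S <- matrix(0, nrow(sp), length(rx),
              dimnames = list(sp$species, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]]), j] <- rx[[j]]
  net <- structure(list(S = S, species = sp, reactions = names(rx),
                        scenario = scenario),
                   class = "reaction_network")
  chk <- check_conservation(net)
  if (max(abs(chk$carbon), abs(chk$electron)) > 1e-9) {
    stop("internal error: network violates carbon/electron conservation")
  }
  net
}

#' Carbon and electron conservation of every reaction
#'
#' @param network A `reaction_network`.
#' @return List with per-reaction `carbon` and `electron` imbalances
#'   (both exactly zero for a valid network, up to 1e-9).
#' @export
check_conservation <- function(network) {
  sp <- network$species
  list(carbon = drop(sp$carbons %*% network$S),
       electron = drop(sp$gamma %*% network$S))
}

# Exact non-negative least squares by exhaustive active-set enumeration.
# The flux systems here have at most 8 unknowns, so enumerating every
# full-rank support set is cheap, deterministic and immune to the
# convergence failures iterative NNLS solvers can hit on strongly
# weighted, degenerate systems. By the KKT conditions the NNLS optimum
# solves the unconstrained problem on its support, so the best feasible
# support attains the global minimum.
.nnls_exact <- function(A, b) {
  n <- ncol(A)
  best <- list(ssr = sum(b^2), x = rep(0, n))  # empty support
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    qrA <- qr(As)
    if (qrA$rank < length(S)) next  # covered by a smaller support
    xs <- qr.coef(qrA, b)
    if (any(xs < -1e-9)) next
    r <- b - As %*% xs
    ssr <- sum(r^2)
    if (ssr < best$ssr - 1e-12 ||
        (ssr < best$ssr + 1e-12 && length(S) < sum(best$x > 0))) {
      x <- rep(0, n)
      x[S] <- pmax(xs, 0)
      best <- list(ssr = ssr, x = x)
    }
  }
  best
}

# Solve v >= 0 minimising ||A v - b|| with internal steady state enforced
# by a large weight; returns fluxes and unweighted boundary residual.
.nnls_fluxes <- function(network, b_boundary, hard = character(0),
                         w_hard = 1e6) {
  S <- network$S
  sp <- network$species
  internal <- sp$species[!sp$boundary]
  rows <- list(); rhs <- numeric(0); n_soft <- 0L
  for (s in sp$species) {
    if (s %in% internal || s %in% hard) {
      w <- w_hard
      target <- if (s %in% names(b_boundary)) b_boundary[[s]] else 0
    } else {
      w <- 1
      target <- if (s %in% names(b_boundary)) b_boundary[[s]] else NA
      if (!is.na(target)) n_soft <- n_soft + 1L
    }
    if (is.na(target)) next  # unconstrained free export
    rows[[length(rows) + 1L]] <- w * S[s, , drop = TRUE]
    rhs <- c(rhs, w * target)
  }
  A <- do.call(rbind, rows)
  if (n_soft == 0L) {
    # every row is a hard constraint: drop the common weight
    A <- A / w_hard
    rhs <- rhs / w_hard
  }
  fit <- .nnls_exact(A, rhs)
  v <- fit$x
  names(v) <- network$reactions
  exports <- drop(S %*% v)
  meas <- intersect(names(b_boundary), sp$species[sp$boundary])
  resid <- sqrt(sum((exports[meas] - unlist(b_boundary[meas]))^2))
  hard_resid <- max(abs(exports[internal]),
                    if (length(hard)) abs(exports[hard] -
                      unlist(b_boundary[hard])) else 0)
  list(fluxes = v, exports = exports, residual = resid,
       hard_residual = hard_resid)
}

.f_wlp_of <- function(v) {
  wlp <- sum(v[intersect(names(v), c("WLP_CO2", "WLP_FOR"))])
  ack <- if ("ACK" %in% names(v)) v[["ACK"]] else 0
  tot <- wlp + ack
  if (tot <= 0) 0 else wlp / tot
}

#' Theoretical product stoichiometry under boundary constraints
#'
#' Solves the steady-state balance of the network per mol of substrate
#' consumed, with chosen boundary fluxes pinned (e.g. no H2, formate or
#' biomass export). With either WLP variant and no H2/formate/biomass
#' export this reproduces the acetogenic overall conversion
#' 1 galacturonate -> 2.5 acetate + 1 CO2.
#'
#' @param network A `reaction_network`.
#' @param constraints Named list of boundary exports to fix, in mol per mol
#'   substrate (e.g. `list(h2 = 0, formate = 0, biomass = 0)`).
#' @param tol Feasibility tolerance on the constrained rows.
#' @return List: `yields` (net boundary exports, mol per mol substrate),
#'   `fluxes`, `f_wlp` (WLP share of total acetate flux), `feasible`,
#'   `residual` (constraint violation norm).
#' @export
theoretical_stoichiometry <- function(network,
                                      constraints = list(h2 = 0, formate = 0,
                                                         biomass = 0),
                                      tol = 1e-6) {
  b <- c(list(galacturonate = -1), constraints)
  sol <- .nnls_fluxes(network, b, hard = names(b))
  feasible <- sol$hard_residual < tol
  if (!feasible) {
    warning("constraint set infeasible for scenario ", network$scenario,
            " (violation ", format(sol$hard_residual, digits = 3), ")")
  }
  yields <- sol$exports[network$species$species[network$species$boundary]]
  yields <- yields[setdiff(names(yields), "galacturonate")]
  list(yields = yields, fluxes = sol$fluxes, f_wlp = .f_wlp_of(sol$fluxes),
       feasible = feasible, residual = sol$hard_residual)
}

#' Infer reaction fluxes from measured yields
#'
#' Converts a yield set to net boundary flows in mol per mol substrate and
#' solves min ||S v - flows||^2 subject to v >= 0 with internal species
#' (pyruvate, acetyl-CoA, electron pairs) held at steady state.
#' Measurement error is absorbed as a least-squares residual over the
#' boundary flows, because measured chemostat yields close the carbon and
#' electron balances only approximately.
#'
#' @param yields A `yield_set` (carbon species in Cmol/Cmol, H2 in
#'   mol/Cmol).
#' @param network A `reaction_network`.
#' @param registry Compound registry for carbon counts.
#' @param substrate Substrate name.
#' @param residual_warn Boundary residual norm above which the result is
#'   flagged (`warn = TRUE`), not an error.
#' @return `flux_vector`: list with `fluxes` (mol per mol substrate),
#'   `f_wlp`, `residual`, `warn`, and the fitted boundary `exports`.
#' @export
infer_fluxes <- function(yields, network, registry = default_registry(),
                         substrate = "galacturonate", residual_warn = 0.25) {
  stopifnot(inherits(yields, "yield_set"),
            inherits(network, "reaction_network"))
  cs <- registry[[substrate]]$carbons
  known <- network$species$species
  bad <- setdiff(yields$compound, c(known, substrate))
  if (length(bad)) {
    stop("yield species absent from network: ", paste(bad, collapse = ", "))
  }
  b <- list(galacturonate = -1)
  for (i in seq_len(nrow(yields))) {
    nm <- yields$compound[i]
    ci <- network$species$carbons[network$species$species == nm]
    b[[nm]] <- if (ci > 0) yields$yield[i] * cs / ci else yields$yield[i] * cs
  }
  sol <- .nnls_fluxes(network, b)
  structure(list(fluxes = sol$fluxes, f_wlp = .f_wlp_of(sol$fluxes),
                 residual = sol$residual, warn = sol$residual > residual_warn,
                 exports = sol$exports),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> mol per mol substrate\n")
  print(round(x$fluxes, 4))
  cat(sprintf("f_WLP = %.4f   boundary residual = %.4f%s\n",
              x$f_wlp, x$residual,
              if (isTRUE(x$warn)) "  [poor fit]" else ""))
  invisible(x)
}

#' Boundary yields implied by a flux vector
#'
#' Forward map used in recovery tests: multiplies the stoichiometric
#' matrix by a flux vector and converts exports back to a `yield_set`.
#'
#' @param fluxes Named non-negative flux vector (mol per mol substrate).
#' @param network A `reaction_network`.
#' @param registry Compound registry.
#' @return `yield_set` of product yields.
#' @export
yields_from_fluxes <- function(fluxes, network,
                               registry = default_registry()) {
  stopifnot(all(fluxes >= 0))
  exports <- drop(network$S %*% fluxes[network$reactions])
  sp <- network$species
  out <- numeric(0)
  for (i in seq_len(nrow(sp))) {
    if (!sp$boundary[i] || sp$species[i] == "galacturonate") next
    nm <- sp$species[i]
    cs <- registry[["galacturonate"]]$carbons
    val <- if (sp$carbons[i] > 0) exports[nm] * sp$carbons[i] / cs
           else exports[nm] / cs
    # per mol substrate -> per Cmol substrate uses |export of substrate|
    scale_sub <- abs(exports[["galacturonate"]])
    out[nm] <- val / scale_sub
  }
  out[out < 0 & out > -1e-9] <- 0  # clamp numerical noise
  yield_set(out, registry = registry)
}
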