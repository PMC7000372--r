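#' Parse an elemental formula string
#'
#' Parses formulas over the elements C, H, O and N into a named count
#' vector. Counts may be decimal, so average biomass compositions such as
#' `"CH1.8O0.5N0.2"` are valid. An omitted count means 1.
#'
#' @param text Formula string, e.g. `"C6H10O7"` or `"CH1.8O0.5N0.2"`.
#' @return Named numeric vector with elements `C`, `H`, `O`, `N` (zero for
#'   absent elements), of class `elemental_formula`.
#' @examples
#' parse_formula("C6H10O7")
#' parse_formula("CH1.8O0.5N0.2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  # elements here are single letters (C, H, O, N), so tokenize per letter
  tokens <- regmatches(text, gregexpr("[A-Za-z]|[0-9]*\\.?[0-9]+", text))[[1]]
  if (paste(tokens, collapse = "") != gsub("[[:space:]]", "", text)) {
    stop("malformed formula '", text, "': unrecognised characters")
  }
  counts <- c(C = 0, H = 0, O = 0, N = 0)
  i <- 1L
  while (i <= length(tokens)) {
    sym <- tokens[i]
    if (!grepl("^[A-Za-z]+$", sym)) {
      stop("malformed formula '", text, "': unexpected token '", sym, "'")
    }
    if (!sym %in% names(counts)) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    }
    n <- 1
    if (i < length(tokens) && grepl("^[0-9.]", tokens[i + 1L])) {
      n <- as.numeric(tokens[i + 1L])
      i <- i + 1L
    }
    counts[sym] <- counts[sym] + n
    i <- i + 1L
  }
  if (any(counts < 0)) stop("negative element count in '", text, "'")
  structure(counts, class = "elemental_formula")
}

#' Degree of reduction of a compound
#'
#' Electron equivalents per mole relative to the CO2/H2O/NH3 reference
#' state: gamma = 4 C + H - 2 O - 3 N (ammonia as nitrogen source). The
#' per-Cmol value divides by the carbon count and is undefined for
#' carbon-free species.
#'
#' @param formula An `elemental_formula` (or string, parsed on the fly).
#' @param nitrogen_source Only `"ammonia"` is supported (valence -3 per N).
#' @return List with `per_mol` and `per_cmol` (the latter `NA` when C = 0).
#' @examples
#' degree_of_reduction("C6H10O7")  # 20 per mol, 3.33 per Cmol
#' degree_of_reduction("CO2")      # fully oxidised: 0
#' @export
degree_of_reduction <- function(formula, nitrogen_source = "ammonia") {
  nitrogen_source <- match.arg(nitrogen_source)
  if (is.character(formula)) formula <- parse_formula(formula)
  f <- unclass(formula)
  per_mol <- 4 * f[["C"]] + f[["H"]] - 2 * f[["O"]] - 3 * f[["N"]]
  per_cmol <- if (f[["C"]] > 0) per_mol / f[["C"]] else NA_real_
  list(per_mol = per_mol, per_cmol = per_cmol)
}

#' Define a chemical compound for balance calculations
#'
#' @param name Compound name used in rate/yield tables.
#' @param formula Formula string or `elemental_formula`.
#' @return Object of class `compound`: name, formula, `carbons`,
#'   `gamma_mol` and `gamma_cmol` (degree of reduction per mol / per Cmol).
#' @export
compound <- function(name, formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  g <- degree_of_reduction(formula)
  structure(
    list(name = name, formula = formula,
         carbons = unname(formula[["C"]]),
         gamma_mol = unname(g$per_mol), gamma_cmol = unname(g$per_cmol)),
    class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s  C=%g  gamma/mol=%g  gamma/Cmol=%s\n",
              x$name, x$carbons, x$gamma_mol,
              ifelse(is.na(x$gamma_cmol), "NA", format(x$gamma_cmol))))
  invisible(x)
}

#' Default compound registry for the galacturonate enrichment culture
#'
#' Registry of the species appearing in the rate and yield tables:
#' D-galacturonate (C6H10O7), acetate, formate, CO2, H2 and average biomass
#' CH1.8O0.5N0.2 (per Cmol, degree of reduction 4.2).
#'
#' @param extra Optional named list `name = formula string` to append.
#' @return Named list of `compound` objects.
#' @export
default_registry <- function(extra = NULL) {
  reg <- list(
    galacturonate = compound("galacturonate", "C6H10O7"),
    acetate       = compound("acetate", "C2H4O2"),
    formate       = compound("formate", "CH2O2"),
    co2           = compound("co2", "CO2"),
    h2            = compound("h2", "H2"),
    biomass       = compound("biomass", "CH1.8O0.5N0.2")
  )
  if (!is.null(extra)) {
    for (nm in names(extra)) reg[[nm]] <- compound(nm, extra[[nm]])
  }
  reg
}

#' Read a compound registry from a YAML file
#'
#' The file maps compound names to formula strings, e.g.
#' `galacturonate: C6H10O7`.
#'
#' @param path Path to a YAML file.
#' @return Named list of `compound` objects.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty compound registry: ", path)
  out <- lapply(names(raw), function(nm) compound(nm, raw[[nm]]))
  names(out) <- names(raw)
  out
}
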