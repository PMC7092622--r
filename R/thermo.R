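#' Thermodynamic table
#'
#' Standard transformed formation energies (pH 7, 25 degC) and redox-couple
#' midpoint potentials used to score net fermentation reactions in kJ/mol.
#'
#' @param delta_gf_prime named numeric, kJ/mol per species id.
#' @param couples named numeric, midpoint potentials E0' in mV.
#' @param constants list with `faraday_kj_per_v`, `rt_kj` (RT in kJ/mol at
#'   25 degC) and `ph`.
#' @param provenance free-text source note.
#' @return an object of class `"gf_thermo"`.
#' @export
thermo_table <- function(delta_gf_prime, couples,
                         constants = list(faraday_kj_per_v = 96.485,
                                          rt_kj = 2.47897, ph = 7),
                         provenance = "") {
  stopifnot(is.numeric(unlist(delta_gf_prime)), is.numeric(unlist(couples)))
  structure(list(delta_gf_prime = as.list(delta_gf_prime),
                 couples = as.list(couples),
                 constants = constants, provenance = provenance),
            class = "gf_thermo")
}

#' Load a thermodynamic table from YAML
#' @param path YAML file; defaults to the bundled table.
#' @return a [thermo_table()].
#' @export
load_thermo_table <- function(path = gasferm_thermo_file()) {
  doc <- yaml::read_yaml(path)
  for (key in c("delta_gf_prime", "couples", "constants"))
    if (is.null(doc[[key]])) stop("thermo file missing key '", key, "'")
  thermo_table(doc$delta_gf_prime, doc$couples, doc$constants,
               if (is.null(doc$provenance)) "" else doc$provenance)
}

# pH correction per mole of free H+ produced: RT ln(10^-pH)
.proton_term <- function(table) {
  -table$constants$rt_kj * log(10) * table$constants$ph
}

#' Standard transformed reaction energy from formation energies
#'
#' DeltaG0' = sum(products) - sum(reactants) of formation energies, with
#' each net free proton produced contributing the pH-7 correction term
#' RT ln(1e-7) ~= -39.96 kJ/mol.  Linear in the stoichiometry.  Electron
#' carriers have no formation-energy entry and must be scored through
#' [redox_delta_g()]; their presence raises an error.
#'
#' @param rx a [reaction()] (free protons, species id `"h"`, handled by the
#'   pH convention).
#' @param table a [thermo_table()].
#' @param network a [metabolic_network()] used to recognise carrier species.
#' @return DeltaG0' in kJ per formula unit of the reaction.
#' @export
reaction_delta_g <- function(rx, table, network = cljungdahlii_core()) {
  g <- 0
  for (sid in names(rx$stoich)) {
    nu <- as.numeric(rx$stoich[[sid]])
    if (nu == 0) next
    if (sid == "h") { g <- g + nu * .proton_term(table); next }
    sp <- network$species[[sid]]
    if (!is.null(sp) && sp$role == "carrier")
      stop("carrier species '", sid, "' cannot be scored from formation ",
           "energies; use redox_delta_g()")
    val <- table$delta_gf_prime[[sid]]
    if (is.null(val))
      stop("no formation-energy entry for species '", sid, "'")
    g <- g + nu * val
  }
  g
}

#' Reaction energy of an electron transfer between two redox couples
#'
#' DeltaG0' = -n F (E0'_acceptor - E0'_donor), potentials in mV.
#'
#' @param donor_couple,acceptor_couple couple ids present in the table
#'   (e.g. `"co2_co"` donating to `"fd"`).
#' @param n_electrons positive integer electrons transferred.
#' @param table a [thermo_table()].
#' @return DeltaG0' in kJ/mol.
#' @export
redox_delta_g <- function(donor_couple, acceptor_couple, n_electrons,
                          table) {
  if (!(n_electrons > 0) || n_electrons != round(n_electrons))
    stop("n_electrons must be a positive integer")
  ed <- table$couples[[donor_couple]]
  ea <- table$couples[[acceptor_couple]]
  if (is.null(ed)) stop("unknown redox couple '", donor_couple, "'")
  if (is.null(ea)) stop("unknown redox couple '", acceptor_couple, "'")
  -n_electrons * table$constants$faraday_kj_per_v * (ea - ed) / 1000
}

#' The seven reference net fermentation equations
#'
#' Net stoichiometries of acetate, ethanol and 2,3-butanediol formation
#' from CO or H2/CO2, plus the two ferredoxin half-couplings (CO oxidation
#' to CO2 reducing Fd, and H2 evolution from reduced Fd), together with
#' their reported standard transformed reaction energies (kJ).
#'
#' @return a list of entries with `reaction`, `expected_kj` and `method`
#'   (`"formation"` or `"couples"`, the latter carrying donor/acceptor ids).
#' @export
reference_reactions <- function() {
  list(
    list(reaction = reaction("net_co_acetate", "net",
                             list(co = -4, h2o = -2, acetate = 1, h = 1,
                                  co2 = 2)),
         expected_kj = -175, method = "formation"),
    list(reaction = reaction("net_h2_acetate", "net",
                             list(h2 = -4, co2 = -2, acetate = 1, h = 1,
                                  h2o = 2)),
         expected_kj = -95, method = "formation"),
    list(reaction = reaction("net_co_ethanol", "net",
                             list(co = -6, h2o = -3, ethanol = 1, co2 = 4)),
         expected_kj = -224, method = "formation"),
    list(reaction = reaction("net_h2_ethanol", "net",
                             list(h2 = -6, co2 = -2, ethanol = 1, h2o = 3)),
         expected_kj = -105, method = "formation"),
    list(reaction = reaction("net_co_butanediol", "net",
                             list(co = -11, h2o = -5, butanediol = 1,
                                  co2 = 7)),
         expected_kj = -388, method = "formation"),
    list(reaction = reaction("net_co_fd", "net",
                             list(co = -1, fd_ox = -1, h2o = -1, h = 2,
                                  co2 = 1, fd_red = 1)),
         expected_kj = -14, method = "couples",
         donor = "co2_co", acceptor = "fd", n = 2),
    list(reaction = reaction("net_fd_h2", "net",
                             list(h = -2, fd_red = -1, h2 = 1, fd_ox = 1)),
         expected_kj = -7, method = "couples",
         donor = "fd", acceptor = "h_h2", n = 2)
  )
}

#' Validate the reference net equations against a thermodynamic table
#'
#' Recomputes each of the seven reference reaction energies (rows 1-5 from
#' formation energies, rows 6-7 from couple potentials via -nF deltaE) and
#' compares with the reported integer values.
#'
#' @param network a [metabolic_network()] (carrier recognition).
#' @param table a [thermo_table()].
#' @param tolerance pass threshold in kJ (default 5, reflecting the integer
#'   rounding of the reported values).
#' @return a data.frame with one row per equation: `id`, `equation`,
#'   `computed_kj`, `expected_kj`, `deviation_kj`, `pass`.
#' @export
validate_table1 <- function(network = cljungdahlii_core(),
                            table = load_thermo_table(), tolerance = 5) {
  rows <- reference_reactions()
  out <- data.frame(id = character(0), equation = character(0),
                    computed_kj = numeric(0), expected_kj = numeric(0),
                    deviation_kj = numeric(0), pass = logical(0),
                    stringsAsFactors = FALSE)
  for (row in rows) {
    g <- if (row$method == "formation")
      reaction_delta_g(row$reaction, table, network)
    else
      redox_delta_g(row$donor, row$acceptor, row$n, table)
    dev <- g - row$expected_kj
    out <- rbind(out, data.frame(
      id = row$reaction$id,
      equation = format_reaction(row$reaction),
      computed_kj = g, expected_kj = row$expected_kj,
      deviation_kj = dev, pass = abs(dev) <= tolerance,
      stringsAsFactors = FALSE))
  }
  out
}
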