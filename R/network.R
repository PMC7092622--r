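#' Species and reactions of a metabolic network
#'
#' A network is a list of species and reactions over them. Species carry an
#' elemental formula (over C, H, O, N, S, P, Fe), a charge, a role and, for
#' redox carriers, the number of electrons the reduced member of the pair
#' transports.  Electron carriers (ferredoxin, NAD(H), NADP(H)) are abstract
#' conjugate pairs: their formulas are empty and they contribute to balance
#' checks only through the electron pseudo-element (2 e- per reduced unit).
#' Phosphate bookkeeping is reduced: ATP is written relative to ADP as a
#' transferable PO3- group and tetrahydrofolate adducts relative to the THF
#' scaffold (minus the substituted N-H), so that every enzymatic reaction in
#' the bundled network closes exactly in C, O, N, P and electrons.
#'
#' @param id short unique token.
#' @param name human-readable name.
#' @param formula named list or vector of non-negative integer element
#'   counts over C, H, O, N, S, P, Fe; may be empty for abstract carriers.
#' @param charge integer formal charge.
#' @param role one of `"feed"`, `"product"`, `"external"`, `"carrier"`,
#'   `"intermediate"`.
#' @param carrier_pair id of the conjugate carrier species (required and
#'   symmetric for `role = "carrier"`).
#' @param electrons electrons carried by this species when it is the reduced
#'   member of a carrier pair (2 for Fd_red, NADH, NADPH; 0 otherwise).
#' @return an object of class `"gf_species"`.
#' @export
species <- function(id, name = id, formula = list(), charge = 0L,
                    role = "intermediate", carrier_pair = NULL,
                    electrons = 0L) {
  role <- match.arg(role, c("feed", "product", "external", "carrier",
                            "intermediate"))
  formula <- unlist(formula)
  if (length(formula) > 0) {
    bad <- setdiff(names(formula), c("C", "H", "O", "N", "S", "P", "Fe"))
    if (length(bad) > 0)
      stop("species '", id, "': unknown element(s) ", paste(bad, collapse = ", "))
    if (any(formula < 0) || any(formula != round(formula)))
      stop("species '", id, "': formula counts must be non-negative integers")
  }
  structure(list(id = id, name = name, formula = as.list(formula),
                 charge = as.integer(charge), role = role,
                 carrier_pair = carrier_pair,
                 electrons = as.integer(electrons)),
            class = "gf_species")
}

#' Define a reaction
#'
#' @param id short unique token.
#' @param enzyme enzyme label (e.g. `"CODH"`, `"AOR"`, `"Rnf"`).
#' @param stoich named list of signed stoichiometric coefficients
#'   (species id -> coefficient; negative = consumed).  Coefficients may be
#'   integers, `"p/q"` strings, or rationals; they are stored exactly.
#' @param protons_translocated signed protons exported across the membrane
#'   per unit flux (positive = exported); exact rational.
#' @param reversible may the reaction carry negative flux?
#' @param note free-text annotation.
#' @return an object of class `"gf_reaction"`.
#' @export
reaction <- function(id, enzyme = id, stoich, protons_translocated = 0,
                     reversible = FALSE, note = "") {
  if (length(stoich) == 0) stop("reaction '", id, "': empty stoichiometry")
  if (is.null(names(stoich)) || any(names(stoich) == ""))
    stop("reaction '", id, "': stoichiometry must be named by species id")
  coef <- lapply(stoich, as_rational)
  structure(list(id = id, enzyme = enzyme, stoich = coef,
                 protons_translocated = as_rational(protons_translocated),
                 reversible = isTRUE(reversible), note = note),
            class = "gf_reaction")
}

#' Assemble and validate a metabolic network
#'
#' Checks id uniqueness, resolvability of all reaction species, and the
#' symmetry of carrier pairings.
#'
#' @param species list of [species()] objects.
#' @param reactions list of [reaction()] objects.
#' @param name network name.
#' @return an object of class `"gf_network"`.
#' @export
metabolic_network <- function(species, reactions, name = "network") {
  sids <- vapply(species, `[[`, "", "id")
  if (anyDuplicated(sids))
    stop("duplicate species id(s): ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(species) <- sids
  names(reactions) <- rids
  for (sp in species) {
    if (sp$role == "carrier") {
      if (is.null(sp$carrier_pair))
        stop("carrier species '", sp$id, "' lacks a carrier_pair")
      mate <- species[[sp$carrier_pair]]
      if (is.null(mate))
        stop("carrier species '", sp$id, "': pair '", sp$carrier_pair,
             "' does not exist")
      if (is.null(mate$carrier_pair) || mate$carrier_pair != sp$id)
        stop("carrier pairing not symmetric for '", sp$id, "'")
    }
  }
  for (rx in reactions) {
    missing <- setdiff(names(rx$stoich), sids)
    if (length(missing) > 0)
      stop("reaction '", rx$id, "' references unknown species: ",
           paste(missing, collapse = ", "))
  }
  structure(list(name = name, species = species, reactions = reactions),
            class = "gf_network")
}

#' @export
print.gf_network <- function(x, ...) {
  cat("Metabolic network '", x$name, "': ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

.formula_count <- function(sp, el) {
  v <- sp$formula[[el]]
  if (is.null(v)) 0 else v
}

#' Degree of reduction of a species
#'
#' Available electrons per molecule computed from the elemental formula:
#' gamma = 4 C + H - 2 O - 3 N + 6 S + 5 P.  Fully oxidised carbon (CO2)
#' scores 0; ethanol scores 12; 2,3-butanediol scores 22.
#'
#' @param sp a [species()] object.
#' @param charge_adjusted subtract the formal charge (an anion retains the
#'   electrons of its extra negative charge); used by the electron-balance
#'   checker so that e.g. acetate- counts 8 electrons.
#' @return integer electron count.
#' @export
degree_of_reduction <- function(sp, charge_adjusted = FALSE) {
  g <- 4 * .formula_count(sp, "C") + .formula_count(sp, "H") -
    2 * .formula_count(sp, "O") - 3 * .formula_count(sp, "N") +
    6 * .formula_count(sp, "S") + 5 * .formula_count(sp, "P")
  if (charge_adjusted) g <- g - sp$charge
  as.integer(g)
}

.species_electrons <- function(sp) {
  degree_of_reduction(sp, charge_adjusted = TRUE) + sp$electrons
}

#' Element and electron balance of a reaction
#'
#' Sums element counts weighted by the signed stoichiometry.  Carriers
#' contribute only through the electron pseudo-element `"e"` (2 electrons
#' per reduced unit); chemical species contribute their charge-adjusted
#' degree of reduction.  Because the bundled reactions omit free protons
#' (as the source schemes do), the hydrogen and charge residuals are
#' reported separately as an informational proton imbalance rather than
#' used for pass/fail; `balanced` considers C, O, N, S, P and `"e"`.
#'
#' @param rx a [reaction()] or reaction id present in `network`.
#' @param network a [metabolic_network()].
#' @return a list with `residuals` (named rational vector over C, O, N, S,
#'   P, e), `h_residual`, `charge_residual`, and logical `balanced`.
#' @export
check_element_balance <- function(rx, network) {
  if (is.character(rx)) {
    rx0 <- network$reactions[[rx]]
    if (is.null(rx0)) stop("unknown reaction id '", rx, "'")
    rx <- rx0
  }
  missing <- setdiff(names(rx$stoich), names(network$species))
  if (length(missing) > 0)
    stop("reaction '", rx$id, "' references unknown species: ",
         paste(missing, collapse = ", "))
  elements <- c("C", "O", "N", "S", "P")
  res <- rational(rep(0, length(elements) + 1))
  names_out <- c(elements, "e")
  h_res <- rational(0); q_res <- rational(0)
  for (sid in names(rx$stoich)) {
    sp <- network$species[[sid]]
    nu <- rx$stoich[[sid]]
    for (t in seq_along(elements))
      res[t] <- res[t] + nu * .formula_count(sp, elements[t])
    res[length(elements) + 1] <-
      res[length(elements) + 1] + nu * .species_electrons(sp)
    if (sp$id != "h") h_res <- h_res + nu * .formula_count(sp, "H")
    q_res <- q_res + nu * sp$charge
  }
  resl <- lapply(seq_along(names_out), function(i) res[i])
  names(resl) <- names_out
  balanced <- all(vapply(resl, function(r) r == 0, TRUE))
  list(residuals = resl, h_residual = h_res, charge_residual = q_res,
       balanced = balanced)
}

#' Stoichiometric matrix of a network
#'
#' One row per species, one column per reaction, exact rational entries;
#' an extra final row `"_H+_translocated"` tallies translocated protons.
#'
#' @param network a [metabolic_network()].
#' @return a list with numerator and denominator matrices (`n`, `d`) and
#'   dimnames (species + proton tally row, reaction columns).
#' @export
build_stoichiometric_matrix <- function(network) {
  sids <- names(network$species)
  rids <- names(network$reactions)
  n <- matrix(0, length(sids) + 1, length(rids),
              dimnames = list(c(sids, "_H+_translocated"), rids))
  d <- matrix(1, length(sids) + 1, length(rids),
              dimnames = dimnames(n))
  for (j in seq_along(rids)) {
    rx <- network$reactions[[j]]
    for (sid in names(rx$stoich)) {
      cf <- rx$stoich[[sid]]
      n[sid, j] <- cf$n; d[sid, j] <- cf$d
    }
    n["_H+_translocated", j] <- rx$protons_translocated$n
    d["_H+_translocated", j] <- rx$protons_translocated$d
  }
  list(n = n, d = d)
}

# --- structured-text (YAML) persistence -----------------------------------

.species_to_list <- function(sp) {
  out <- list(id = sp$id, name = sp$name, formula = sp$formula,
              charge = sp$charge, role = sp$role)
  if (!is.null(sp$carrier_pair)) out$carrier_pair <- sp$carrier_pair
  if (sp$electrons != 0) out$electrons <- sp$electrons
  out
}

.reaction_to_list <- function(rx) {
  st <- lapply(rx$stoich, function(cf) as.character(cf))
  list(id = rx$id, enzyme = rx$enzyme, stoich = st,
       protons_translocated = as.character(rx$protons_translocated),
       reversible = rx$reversible, note = rx$note)
}

#' Write a network to a YAML document
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @export
save_network <- function(network, path) {
  doc <- list(name = network$name,
              species = lapply(unname(network$species), .species_to_list),
              reactions = lapply(unname(network$reactions), .reaction_to_list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a network from a YAML document
#'
#' Schema: top-level keys `name`, `species` (list of id/name/formula/charge/
#' role/carrier_pair/electrons) and `reactions` (list of id/enzyme/stoich/
#' protons_translocated/reversible/note).  Validation failures name the
#' offending field.
#'
#' @param path YAML file path.
#' @return a validated [metabolic_network()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (key in c("name", "species", "reactions"))
    if (is.null(doc[[key]])) stop("network file missing top-level key '", key, "'")
  sp <- lapply(doc$species, function(s) {
    if (is.null(s$id)) stop("species entry without 'id'")
    species(id = s$id, name = if (is.null(s$name)) s$id else s$name,
            formula = if (is.null(s$formula)) list() else s$formula,
            charge = if (is.null(s$charge)) 0L else s$charge,
            role = if (is.null(s$role)) "intermediate" else s$role,
            carrier_pair = s$carrier_pair,
            electrons = if (is.null(s$electrons)) 0L else s$electrons)
  })
  rx <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without 'id'")
    if (is.null(r$stoich)) stop("reaction '", r$id, "' missing 'stoich'")
    reaction(id = r$id, enzyme = if (is.null(r$enzyme)) r$id else r$enzyme,
             stoich = r$stoich,
             protons_translocated = if (is.null(r$protons_translocated)) 0
                                    else r$protons_translocated,
             reversible = isTRUE(r$reversible),
             note = if (is.null(r$note)) "" else r$note)
  })
  metabolic_network(sp, rx, name = doc$name)
}

#' Compare two networks for equality (ids, formulas, exact coefficients)
#' @param a,b networks.
#' @return logical.
#' @export
networks_equal <- function(a, b) {
  if (!identical(sort(names(a$species)), sort(names(b$species)))) return(FALSE)
  if (!identical(sort(names(a$reactions)), sort(names(b$reactions)))) return(FALSE)
  for (id in names(a$species)) {
    x <- a$species[[id]]; y <- b$species[[id]]
    fstr <- function(f) {
      f <- unlist(f)
      if (is.null(f) || length(f) == 0) return(character(0))
      f <- f[f != 0]
      sort(paste0(names(f), "=", as.numeric(f)))
    }
    if (!identical(fstr(x$formula), fstr(y$formula))) return(FALSE)
    if (x$charge != y$charge || x$role != y$role ||
        x$electrons != y$electrons) return(FALSE)
    if (!identical(x$carrier_pair, y$carrier_pair)) return(FALSE)
  }
  for (id in names(a$reactions)) {
    x <- a$reactions[[id]]; y <- b$reactions[[id]]
    if (!identical(sort(names(x$stoich)), sort(names(y$stoich)))) return(FALSE)
    for (sid in names(x$stoich))
      if (!(x$stoich[[sid]] == y$stoich[[sid]])) return(FALSE)
    if (!(x$protons_translocated == y$protons_translocated)) return(FALSE)
    if (x$reversible != y$reversible) return(FALSE)
  }
  TRUE
}
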