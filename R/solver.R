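#' Scheme presets
#'
#' A preset names a feed gas, a product demand (the normalization basis),
#' the set of active reactions, expected flux directions, optional flux
#' ties between reactions, and the chemiosmotic parameters.  The bundled
#' presets encode the published CO and H2/CO2 growth schemes.
#'
#' @param name preset token.
#' @param feed `"CO"` or `"H2_CO2"`.
#' @param product_demand named list of product moles (exact rationals or
#'   `"p/q"` strings), the basis the solution is normalized to.
#' @param active character vector of active reaction ids.
#' @param direction named character vector; `"forward"` requires
#'   non-negative flux, `"reverse"` non-positive (e.g. CODH running toward
#'   CO on H2/CO2, AOR reducing acetate on CO).
#' @param ties list of `list(a=, b=, ratio=)` constraints `v_a = ratio*v_b`
#'   (e.g. equal flux through the two acetate-forming routes of the H2
#'   scheme).
#' @param assumptions character flags documenting the scheme variant.
#' @param rnf_h_per_fd protons exported by Rnf per reduced ferredoxin
#'   oxidized (default 2).
#' @param h_per_atp protons consumed by the ATP synthase per ATP (default 4).
#' @return an object of class `"gf_preset"`.
#' @export
scheme_preset <- function(name, feed, product_demand, active,
                          direction = character(0), ties = list(),
                          assumptions = character(0),
                          rnf_h_per_fd = 2, h_per_atp = 4) {
  feed <- match.arg(feed, c("CO", "H2_CO2"))
  if (length(product_demand) == 0) stop("preset '", name, "': empty product demand")
  structure(list(name = name, feed = feed,
                 product_demand = lapply(product_demand, as_rational),
                 active = active,
                 direction = direction, ties = ties,
                 assumptions = assumptions,
                 rnf_h_per_fd = as_rational(rnf_h_per_fd),
                 h_per_atp = as_rational(h_per_atp)),
            class = "gf_preset")
}

#' Load scheme presets from a YAML file
#'
#' @param path YAML file; defaults to the bundled preset collection.
#' @return named list of [scheme_preset()] objects.
#' @export
load_presets <- function(path = gasferm_preset_file()) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$presets)) stop("preset file missing top-level key 'presets'")
  out <- lapply(doc$presets, function(p) {
    scheme_preset(name = p$name, feed = p$feed,
                  product_demand = p$product_demand,
                  active = unlist(p$active),
                  direction = if (is.null(p$direction)) character(0)
                              else unlist(p$direction),
                  ties = if (is.null(p$ties)) list() else p$ties,
                  assumptions = if (is.null(p$assumptions)) character(0)
                                else unlist(p$assumptions),
                  rnf_h_per_fd = if (is.null(p$rnf_h_per_fd)) 2 else p$rnf_h_per_fd,
                  h_per_atp = if (is.null(p$h_per_atp)) 4 else p$h_per_atp)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Fetch one bundled preset by name
#' @param name preset token, e.g. `"H2_ACETATE"` or `"CO_FULL"`.
#' @return a [scheme_preset()].
#' @export
get_preset <- function(name) {
  presets <- load_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; bundled presets: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

# species whose pool is tallied rather than balanced (net ATP accumulates)
.POOL_SPECIES <- c("atp", "adp")

.exchange_species <- function(network, preset) {
  ext <- names(Filter(function(s) s$role == "external", network$species))
  feed <- switch(preset$feed, CO = "co", H2_CO2 = "h2")
  c(ext, feed)
}

#' Solve the steady-state flux distribution of a scheme
#'
#' Balances every internal species (carriers and intermediates) exactly at
#' zero, fixes product exchange to the preset demand, balances the
#' proton-motive tally (protons exported by Rnf equal protons consumed by
#' the ATP synthase) and solves the resulting linear system in exact
#' rational arithmetic with a deterministic pivot order.  Uniqueness is
#' verified; an underdetermined system falls back to a flagged minimum-norm
#' solution, and an infeasible demand produces an error naming the
#' unbalanced carrier pools.
#'
#' @param network a [metabolic_network()].
#' @param preset a [scheme_preset()] or bundled preset name.
#' @param rnf_h_per_fd,h_per_atp chemiosmotic parameter overrides; defaults
#'   come from the preset.
#' @return an object of class `"gf_flux"` with exact rational fluxes, the
#'   gross proton export, substrate-level and net ATP tallies, and the
#'   exchange coefficients of all external species.
#' @export
solve_scheme <- function(network, preset, rnf_h_per_fd = NULL,
                         h_per_atp = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  rnf_h <- if (is.null(rnf_h_per_fd)) preset$rnf_h_per_fd
           else as_rational(rnf_h_per_fd)
  h_atp <- if (is.null(h_per_atp)) preset$h_per_atp else as_rational(h_per_atp)
  if (!(h_atp > 0)) stop("h_per_atp must be positive")
  if (rnf_h < 0) stop("rnf_h_per_fd must be non-negative")

  missing_rx <- setdiff(preset$active, names(network$reactions))
  if (length(missing_rx) > 0)
    stop("preset '", preset$name, "' activates unknown reaction(s): ",
         paste(missing_rx, collapse = ", "))
  prods <- names(preset$product_demand)
  missing_p <- setdiff(prods, names(network$species))
  if (length(missing_p) > 0)
    stop("preset '", preset$name, "' demands unknown product(s): ",
         paste(missing_p, collapse = ", "))

  reactions <- network$reactions[preset$active]
  # apply chemiosmotic parameters to the membrane machines
  for (id in names(reactions)) {
    if (id == "rnf") reactions[[id]]$protons_translocated <- rnf_h
    if (id == "atps") reactions[[id]]$protons_translocated <- -h_atp
  }

  exch <- .exchange_species(network, preset)
  sids <- names(network$species)
  balanced <- setdiff(sids, c(exch, .POOL_SPECIES, prods))

  nr <- length(reactions)
  touch <- function(sid) vapply(reactions, function(rx)
    !is.null(rx$stoich[[sid]]), TRUE)
  coef_row <- function(sid) {
    n <- numeric(nr); d <- rep(1, nr)
    for (j in seq_len(nr)) {
      cf <- reactions[[j]]$stoich[[sid]]
      if (!is.null(cf)) { n[j] <- cf$n; d[j] <- cf$d }
    }
    list(n = n, d = d)
  }

  rows_n <- NULL; rows_d <- NULL; row_lab <- character(0)
  b <- rational(numeric(0))
  for (sid in balanced) {
    if (!any(touch(sid))) next
    cr <- coef_row(sid)
    rows_n <- rbind(rows_n, cr$n); rows_d <- rbind(rows_d, cr$d)
    row_lab <- c(row_lab, sid); b <- c(b, rational(0))
  }
  for (sid in prods) {
    cr <- coef_row(sid)
    rows_n <- rbind(rows_n, cr$n); rows_d <- rbind(rows_d, cr$d)
    row_lab <- c(row_lab, sid)
    b <- c(b, preset$product_demand[[sid]])
  }
  # proton-motive closure
  pn <- numeric(nr); pd <- rep(1, nr)
  for (j in seq_len(nr)) {
    t <- reactions[[j]]$protons_translocated
    pn[j] <- t$n; pd[j] <- t$d
  }
  if (any(pn != 0)) {
    rows_n <- rbind(rows_n, pn); rows_d <- rbind(rows_d, pd)
    row_lab <- c(row_lab, "_pmf"); b <- c(b, rational(0))
  }
  # flux ties
  for (tie in preset$ties) {
    n <- numeric(nr); d <- rep(1, nr)
    ia <- match(tie$a, names(reactions)); ib <- match(tie$b, names(reactions))
    if (is.na(ia) || is.na(ib))
      stop("tie references inactive reaction: ", tie$a, " / ", tie$b)
    ratio <- as_rational(if (is.null(tie$ratio)) 1 else tie$ratio)
    n[ia] <- 1
    n[ib] <- -ratio$n; d[ib] <- ratio$d
    rows_n <- rbind(rows_n, n); rows_d <- rbind(rows_d, d)
    row_lab <- c(row_lab, paste0("_tie:", tie$a, "=", tie$b))
    b <- c(b, rational(0))
  }

  sol <- rational_solve(list(n = rows_n, d = rows_d), b)
  flagged <- FALSE
  if (sol$status == "inconsistent") {
    carriers <- .diagnose_infeasibility(rows_n, rows_d, b, row_lab, network,
                                        sol$bad_rows)
    stop("infeasible demand for preset '", preset$name,
         "': no steady-state flux distribution balances ",
         paste(carriers, collapse = ", "))
  } else if (sol$status == "underdetermined") {
    # flagged minimum-norm fallback (numeric); bundled presets never reach it
    A <- rows_n / rows_d
    bb <- as.numeric(b)
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * max(sv$d) * 1e-12
    v <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% bb) / sv$d[pos])
    flux <- as_rational(round(drop(v), 6))
    flagged <- TRUE
  } else {
    flux <- sol$x
  }
  names(flux$n) <- names(reactions); names(flux$d) <- names(reactions)

  # direction constraints
  viol <- character(0)
  for (j in seq_len(nr)) {
    id <- names(reactions)[j]
    f <- flux[j]
    dirn <- if (id %in% names(preset$direction)) preset$direction[[id]]
            else if (!reactions[[j]]$reversible) "forward" else "free"
    if (dirn == "forward" && f < 0) viol <- c(viol, id)
    if (dirn == "reverse" && f > 0) viol <- c(viol, id)
  }
  if (length(viol) > 0)
    stop("direction constraint violated for reaction(s): ",
         paste(viol, collapse = ", "))

  # tallies
  unname_rat <- function(x) { x$n <- unname(x$n); x$d <- unname(x$d); x }
  dot_row <- function(sid) {
    acc <- rational(0)
    for (j in seq_len(nr)) {
      cf <- reactions[[j]]$stoich[[sid]]
      if (!is.null(cf)) acc <- acc + cf * flux[j]
    }
    unname_rat(acc)
  }
  pumped <- rational(0); slp <- rational(0)
  for (j in seq_len(nr)) {
    t <- reactions[[j]]$protons_translocated
    if (t > 0) pumped <- pumped + t * flux[j]
    if (names(reactions)[j] != "atps") {
      cf <- reactions[[j]]$stoich[["atp"]]
      if (!is.null(cf)) slp <- slp + cf * flux[j]
    }
  }
  pumped <- unname_rat(pumped); slp <- unname_rat(slp)
  net_atp <- dot_row("atp")

  exchange <- list()
  for (sid in sids) {
    e <- dot_row(sid)
    if (sid %in% c(exch, prods, .POOL_SPECIES)) {
      if (!(e == 0)) exchange[[sid]] <- e
    } else if (!(e == 0)) {
      stop("internal species '", sid, "' not balanced (solver bug)")
    }
  }

  structure(list(preset = preset, network = network, flux = flux,
                 reactions = reactions,
                 pumped_protons = pumped, substrate_level_atp = slp,
                 net_atp = net_atp,
                 chemiosmotic_atp = net_atp - slp,
                 rnf_h_per_fd = rnf_h, h_per_atp = h_atp,
                 exchange = exchange, flagged = flagged),
            class = "gf_flux")
}

# find a minimal set of carrier pools (conjugate pairs treated as one pool)
# whose removal restores feasibility
.diagnose_infeasibility <- function(rows_n, rows_d, b, row_lab, network,
                                    bad_rows) {
  is_carrier <- vapply(row_lab, function(l) {
    sp <- network$species[[l]]
    !is.null(sp) && sp$role == "carrier"
  }, TRUE)
  pool_of <- vapply(row_lab, function(l) {
    sp <- network$species[[l]]
    if (is.null(sp) || sp$role != "carrier") return("")
    paste(sort(c(l, sp$carrier_pair)), collapse = "/")
  }, "")
  pools <- unique(pool_of[is_carrier])
  feasible_without <- function(pool_set) {
    keep <- which(!pool_of %in% pool_set)
    s <- rational_solve(list(n = rows_n[keep, , drop = FALSE],
                             d = rows_d[keep, , drop = FALSE]), b[keep])
    s$status != "inconsistent"
  }
  for (p in pools) if (feasible_without(p)) return(p)
  if (length(pools) >= 2) {
    combos <- utils::combn(pools, 2)
    for (k in seq_len(ncol(combos)))
      if (feasible_without(combos[, k])) return(combos[, k])
  }
  unique(row_lab[intersect(bad_rows, seq_along(row_lab))])
}

#' @export
print.gf_flux <- function(x, ...) {
  cat("Flux distribution for preset '", x$preset$name, "' (feed ",
      x$preset$feed, ")\n", sep = "")
  nz <- which(x$flux$n != 0)
  fl <- as.character(x$flux)
  for (j in nz)
    cat(sprintf("  %-10s %s\n", names(x$flux$n)[j], fl[j]))
  cat("  substrate-level ATP: ", as.character(x$substrate_level_atp),
      "\n  H+ exported:         ", as.character(x$pumped_protons),
      "\n  net ATP:             ", as.character(x$net_atp), "\n", sep = "")
  invisible(x)
}

#' Net ATP yield of a solved scheme
#'
#' Net ATP on the preset's product basis: substrate-level ATP plus exported
#' protons divided by the ATP-synthase stoichiometry.  With the parameters
#' used at solve time this equals the solver's own net-ATP tally (asserted
#' in the test suite).
#'
#' @param dist a [solve_scheme()] result.
#' @param h_per_atp protons per ATP; defaults to the value used in the solve.
#' @return exact rational ATP yield.
#' @export
atp_yield <- function(dist, h_per_atp = NULL) {
  h <- if (is.null(h_per_atp)) dist$h_per_atp else as_rational(h_per_atp)
  if (!(h > 0)) stop("h_per_atp must be positive")
  dist$substrate_level_atp + dist$pumped_protons / h
}

#' Net overall reaction of a solved scheme
#'
#' Collapses the flux distribution into one net exchange reaction over the
#' external species.  By default the accumulated ATP is discharged
#' (n x \[ADP + Pi -> ATP + H2O\] subtracted) so the result is the bare
#' catabolic stoichiometry, directly comparable with the net fermentation
#' equations; free protons are restored from the charge balance.
#'
#' @param dist a [solve_scheme()] result.
#' @param discharge_atp subtract the ATP-synthesis side reaction (default).
#' @return a [reaction()] whose stoichiometry is the net exchange.
#' @export
net_overall_reaction <- function(dist, discharge_atp = TRUE) {
  ex <- dist$exchange
  if (length(ex) == 0)
    return(reaction("net", "net", list(h2o = 0), note = "zero flux"))
  if (discharge_atp && !is.null(ex[["atp"]])) {
    n <- ex[["atp"]]
    adjs <- list(atp = -1, h2o = -1, adp = 1, pi = 1)
    for (sid in names(adjs)) {
      cur <- if (is.null(ex[[sid]])) rational(0) else ex[[sid]]
      ex[[sid]] <- cur + n * adjs[[sid]]
    }
  }
  # restore the free protons omitted from the enzyme reactions: the net
  # exchange must be charge-neutral
  q <- rational(0)
  for (sid in setdiff(names(ex), "h"))
    q <- q + ex[[sid]] * dist$network$species[[sid]]$charge
  ex[["h"]] <- rational(0) - q
  ex <- Filter(function(cf) !(cf == 0), ex)
  if (length(ex) == 0) ex <- list(h2o = 0)
  reaction(paste0("net_", dist$preset$name), "net scheme reaction", ex,
           note = paste("net exchange of preset", dist$preset$name))
}

#' Format a reaction as a chemical equation string
#' @param rx a [reaction()].
#' @param network optional network for species display names.
#' @return a single string like `"4 h2 + 2 co2 -> 1 acetate + 1 h + 2 h2o"`.
#' @export
format_reaction <- function(rx, network = NULL) {
  lhs <- character(0); rhs <- character(0)
  for (sid in names(rx$stoich)) {
    cf <- rx$stoich[[sid]]
    if (cf == 0) next
    term <- paste(as.character(abs(cf)), sid)
    if (cf < 0) lhs <- c(lhs, term) else rhs <- c(rhs, term)
  }
  paste(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "))
}

#' Redox closure of a solved scheme
#'
#' Independent re-check that every redox-carrier pool (ferredoxin, NAD,
#' NADP) has exactly zero net production under the solved fluxes; non-zero
#' entries indicate a mis-specified scheme.
#'
#' @param dist a [solve_scheme()] result.
#' @return named list (pair label -> exact rational net production of the
#'   reduced member).
#' @export
redox_closure <- function(dist) {
  net <- dist$network
  reduced <- Filter(function(s) s$role == "carrier" && s$electrons > 0,
                    net$species)
  out <- list()
  for (sp in reduced) {
    acc <- rational(0)
    for (j in seq_along(dist$reactions)) {
      cf <- dist$reactions[[j]]$stoich[[sp$id]]
      if (!is.null(cf)) acc <- acc + cf * dist$flux[j]
    }
    out[[paste0(sp$carrier_pair, "/", sp$id)]] <- acc
  }
  out
}

#' Scale the product demand of a preset
#' @param preset a [scheme_preset()].
#' @param k rational scale factor.
#' @return a new preset with demand multiplied by `k`.
#' @export
scale_preset <- function(preset, k) {
  k <- as_rational(k)
  preset$product_demand <- lapply(preset$product_demand, function(d) d * k)
  preset$name <- paste0(preset$name, "_x", as.character(k))
  preset
}
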