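#' The bundled C. ljungdahlii central-metabolism network
#'
#' Builds the species/reaction model of the Wood-Ljungdahl pathway plus the
#' product branches (acetate via Pta/Ack, ethanol via AOR/AdhE, lactate,
#' 2,3-butanediol via acetolactate) and the energy-conserving machinery
#' (electron-bifurcating hydrogenase, Nfn transhydrogenase, Rnf complex,
#' ATP synthase) used by the CO and H2/CO2 feed schemes.
#'
#' Conventions: electron carriers are abstract conjugate pairs carrying two
#' electrons per reduced unit; free protons are omitted from the individual
#' enzyme reactions (tracked as charge bookkeeping and as the
#' translocated-proton tally); ATP is written relative to ADP as a
#' transferable PO3- group and the tetrahydrofolate C1 adducts relative to
#' the THF scaffold, so every reaction closes exactly in C, O, N, P and
#' electrons.  Cyclohydrolase and methylene-THF dehydrogenase are lumped
#' into a single NADPH-dependent step; the methylene-THF reductase is
#' electron-bifurcating (2 NADH in, one methyl group plus one reduced
#' ferredoxin out).
#'
#' @return a validated [metabolic_network()].
#' @export
cljungdahlii_core <- function() {
  sp <- list(
    species("co",  "carbon monoxide", list(C = 1, O = 1), 0L, "feed"),
    species("h2",  "dihydrogen", list(H = 2), 0L, "feed"),
    species("co2", "carbon dioxide", list(C = 1, O = 2), 0L, "external"),
    species("h2o", "water", list(H = 2, O = 1), 0L, "external"),
    species("h",   "proton", list(H = 1), 1L, "external"),
    species("pi",  "inorganic phosphate (HPO4 2-)",
            list(H = 1, O = 4, P = 1), -2L, "external"),
    species("acetate", "acetate", list(C = 2, H = 3, O = 2), -1L, "product"),
    species("ethanol", "ethanol", list(C = 2, H = 6, O = 1), 0L, "product"),
    species("butanediol", "2,3-butanediol",
            list(C = 4, H = 10, O = 2), 0L, "product"),
    species("lactate", "lactate", list(C = 3, H = 5, O = 3), -1L, "product"),
    species("formate", "formate", list(C = 1, H = 1, O = 2), -1L),
    species("thf", "tetrahydrofolate scaffold", list(), 0L),
    species("formyl_thf", "10-formyl-THF (CHO adduct, minus N-H)",
            list(C = 1, O = 1), 0L),
    species("methylene_thf", "5,10-methylene-THF (CH2 bridge, minus 2 N-H)",
            list(C = 1), 0L),
    species("methyl_thf", "5-methyl-THF (CH3 adduct, minus N-H)",
            list(C = 1, H = 2), 0L),
    species("coa", "coenzyme A (thiol scaffold)", list(), 0L),
    species("acetyl_coa", "acetyl-CoA (acyl adduct, minus thiol H)",
            list(C = 2, H = 2, O = 1), 0L),
    species("acetyl_p", "acetyl phosphate", list(C = 2, H = 3, O = 5, P = 1),
            -2L),
    species("acetaldehyde", "acetaldehyde", list(C = 2, H = 4, O = 1), 0L),
    species("pyruvate", "pyruvate", list(C = 3, H = 3, O = 3), -1L),
    species("acetolactate", "2-acetolactate", list(C = 5, H = 7, O = 4), -1L),
    species("acetoin", "acetoin", list(C = 4, H = 8, O = 2), 0L),
    species("fd_ox",  "oxidized ferredoxin", list(), 0L, "carrier", "fd_red"),
    species("fd_red", "reduced ferredoxin", list(), 0L, "carrier", "fd_ox",
            electrons = 2L),
    species("nad",  "NAD+",  list(), 0L, "carrier", "nadh"),
    species("nadh", "NADH",  list(), 0L, "carrier", "nad", electrons = 2L),
    species("nadp",  "NADP+",  list(), 0L, "carrier", "nadph"),
    species("nadph", "NADPH", list(), 0L, "carrier", "nadp", electrons = 2L),
    species("adp", "ADP (phosphoryl-acceptor scaffold)", list(), 0L,
            "carrier", "atp"),
    species("atp", "ATP (ADP + transferable PO3-)", list(O = 3, P = 1), -1L,
            "carrier", "adp")
  )

  rx <- list(
    reaction("codh", "CODH (carbon monoxide dehydrogenase)",
             list(co = -1, h2o = -1, fd_ox = -1, co2 = 1, fd_red = 1),
             reversible = TRUE,
             note = "CO oxidation to CO2 with ferredoxin; runs in reverse on H2/CO2 to supply the carbonyl CO"),
    reaction("hyt", "electron-bifurcating NADP-specific hydrogenase",
             list(h2 = -2, fd_ox = -1, nadp = -1, fd_red = 1, nadph = 1),
             note = "2 H2 split between ferredoxin and NADP+ by flavin-based bifurcation"),
    reaction("fdh", "formate dehydrogenase (NADPH-coupled)",
             list(co2 = -1, nadph = -1, formate = 1, nadp = 1),
             note = "CO2 reduction to formate; complexed with the bifurcating hydrogenase on H2"),
    reaction("hdcr", "H2-dependent CO2 reductase (cofactor-free variant)",
             list(co2 = -1, h2 = -1, formate = 1),
             note = "alternative methyl-branch entry; inactive in the default H2 scheme"),
    reaction("fts", "formyl-THF synthetase",
             list(formate = -1, thf = -1, atp = -1,
                  formyl_thf = 1, adp = 1, pi = 1),
             note = "ATP-consuming formate activation"),
    reaction("mthfd", "methenyl-THF cyclohydrolase + methylene-THF dehydrogenase (lumped, NADPH)",
             list(formyl_thf = -1, nadph = -1,
                  methylene_thf = 1, nadp = 1, h2o = 1)),
    reaction("mthfr", "electron-bifurcating methylene-THF reductase",
             list(methylene_thf = -1, nadh = -2, fd_ox = -1,
                  methyl_thf = 1, nad = 2, fd_red = 1),
             note = "2 NADH bifurcated between the methyl group and ferredoxin"),
    reaction("acs", "CO dehydrogenase / acetyl-CoA synthase",
             list(methyl_thf = -1, co = -1, coa = -1,
                  acetyl_coa = 1, thf = 1)),
    reaction("pta", "phosphotransacetylase (Pta)",
             list(acetyl_coa = -1, pi = -1, acetyl_p = 1, coa = 1)),
    reaction("ack", "acetate kinase (Ack)",
             list(acetyl_p = -1, adp = -1, acetate = 1, atp = 1),
             note = "substrate-level phosphorylation"),
    reaction("adhe_ald", "AdhE aldehyde dehydrogenase (CoA-acylating, NADH)",
             list(acetyl_coa = -1, nadh = -1,
                  acetaldehyde = 1, nad = 1, coa = 1)),
    reaction("adh_etoh", "alcohol dehydrogenase (NADPH)",
             list(acetaldehyde = -1, nadph = -1, ethanol = 1, nadp = 1)),
    reaction("aor", "AOR (aldehyde:ferredoxin oxidoreductase)",
             list(acetaldehyde = -1, h2o = -1, fd_ox = -1,
                  acetate = 1, fd_red = 1),
             reversible = TRUE,
             note = "oxidative as written; reverse (acetate reduction) carries ethanol flux on CO"),
    reaction("pfor", "PFOR (pyruvate:ferredoxin oxidoreductase)",
             list(acetyl_coa = -1, co2 = -1, fd_red = -1,
                  pyruvate = 1, coa = 1, fd_ox = 1),
             reversible = TRUE,
             note = "written in the pyruvate-synthase direction"),
    reaction("ldh", "lactate dehydrogenase (LdhA)",
             list(pyruvate = -1, nadh = -1, lactate = 1, nad = 1)),
    reaction("als", "acetolactate synthase",
             list(pyruvate = -2, acetolactate = 1, co2 = 1)),
    reaction("aldc", "acetolactate decarboxylase (ALDC)",
             list(acetolactate = -1, acetoin = 1, co2 = 1)),
    reaction("bdh", "2,3-butanediol dehydrogenase (23BDH, NADH)",
             list(acetoin = -1, nadh = -1, butanediol = 1, nad = 1)),
    reaction("nfn", "Nfn (electron-bifurcating transhydrogenase)",
             list(fd_red = -1, nadh = -1, nadp = -2,
                  fd_ox = 1, nad = 1, nadph = 2),
             reversible = TRUE),
    reaction("rnf", "Rnf complex (proton-translocating Fd:NAD+ oxidoreductase)",
             list(fd_red = -1, nad = -1, fd_ox = 1, nadh = 1),
             protons_translocated = 2,
             note = "exports 2 H+ per reduced ferredoxin oxidized"),
    reaction("atps", "ATP synthase",
             list(adp = -1, pi = -1, atp = 1, h2o = 1),
             protons_translocated = -4,
             note = "consumes 4 H+ of the gradient per ATP")
  )

  metabolic_network(sp, rx, name = "cljungdahlii_core")
}

#' Path to the bundled network file
#' @return file path of the installed YAML network definition.
#' @export
gasferm_network_file <- function() {
  system.file("extdata", "cljungdahlii_core.yaml", package = "gasferm",
              mustWork = TRUE)
}

#' Path to the bundled thermodynamic table file
#' @return file path of the installed YAML thermo table.
#' @export
gasferm_thermo_file <- function() {
  system.file("extdata", "thermo_default.yaml", package = "gasferm",
              mustWork = TRUE)
}

#' Path to the bundled scheme preset file
#' @return file path of the installed YAML preset collection.
#' @export
gasferm_preset_file <- function() {
  system.file("extdata", "presets.yaml", package = "gasferm",
              mustWork = TRUE)
}
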