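# Small fixtures shared across test files; everything is built in code.

# a minimal two-species conversion network (A -> B)
tiny_network <- function() {
  metabolic_network(
    list(species("A", formula = list(C = 1, O = 2)),
         species("B", formula = list(C = 1, O = 2))),
    list(reaction("r1", "isomerase", list(A = -1, B = 1))),
    name = "tiny")
}

# the published net fermentation stoichiometries appended to the bundled
# network as single net reactions (for balance and matrix tests)
network_with_net_rows <- function() {
  net <- cljungdahlii_core()
  refs <- reference_reactions()
  rx <- c(net$reactions, lapply(refs, `[[`, "reaction"))
  metabolic_network(net$species, rx, name = "core_plus_net_rows")
}

expect_rational_equal <- function(x, y) {
  expect_true(is_rational(x))
  expect_true(all(x == as_rational(y)))
}
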