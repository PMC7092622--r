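# Scheme presets for the bundled C. ljungdahlii core network.
# Chemiosmotic defaults: Rnf exports 2 H+ per reduced ferredoxin oxidized,
# ATP synthase consumes 4 H+ per ATP.
presets:
  - name: H2_ACETATE
    feed: H2_CO2
    product_demand: {acetate: 1}
    active: [hyt, fdh, fts, mthfd, mthfr, codh, acs, pta, ack, adhe_ald,
             aor, nfn, rnf, atps]
    direction: {codh: reverse, aor: forward}
    ties:
      - {a: ack, b: aor, ratio: 1}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch,
                  acetate-via-ack-and-aor]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: H2_ACETATE_HDCR
    feed: H2_CO2
    product_demand: {acetate: 1}
    active: [hyt, hdcr, fts, mthfd, mthfr, codh, acs, pta, ack, adhe_ald,
             aor, nfn, rnf, atps]
    direction: {codh: reverse, aor: forward}
    ties:
      - {a: ack, b: aor, ratio: 1}
    assumptions: [bifurcating-mthfr, hdcr-formate, acetate-via-ack-and-aor]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_ACETATE
    feed: CO
    product_demand: {acetate: 1}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pta, ack, nfn, rnf, atps]
    direction: {codh: forward}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch, acetate-only]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_ETHANOL
    feed: CO
    product_demand: {ethanol: 1}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pta, ack, aor, adh_etoh,
             nfn, rnf, atps]
    direction: {codh: forward, aor: reverse}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch, ethanol-via-aor]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_BDO
    feed: CO
    product_demand: {butanediol: 1}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pfor, als, aldc, bdh,
             nfn, rnf, atps]
    direction: {codh: forward}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_ACETATE_BDO
    feed: CO
    product_demand: {acetate: 1, butanediol: 1}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pta, ack, pfor, als, aldc,
             bdh, nfn, rnf, atps]
    direction: {codh: forward}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_FULL
    feed: CO
    product_demand: {acetate: 1, butanediol: 1, ethanol: 4}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pta, ack, aor, adh_etoh,
             pfor, als, aldc, bdh, nfn, rnf, atps]
    direction: {codh: forward, aor: reverse}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch, ethanol-via-aor]
    rnf_h_per_fd: 2
    h_per_atp: 4
  - name: CO_FULL_ADHE
    feed: CO
    product_demand: {acetate: 1, butanediol: 1, ethanol: 4}
    active: [codh, fdh, fts, mthfd, mthfr, acs, pta, ack, adhe_ald,
             adh_etoh, pfor, als, aldc, bdh, nfn, rnf, atps]
    direction: {codh: forward}
    assumptions: [bifurcating-mthfr, nadph-methyl-branch, ethanol-via-adhe]
    rnf_h_per_fd: 2
    h_per_atp: 4
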