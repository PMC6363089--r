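#' The Calvin-Benson-Bassham network definition for Synechocystis
#'
#' Programmatic constructor of the shipped 29-reaction model of the CBB cycle
#' embedded in Synechocystis central carbon metabolism: the 13 catalytic CBB
#' steps (Rubisco, pgk, gapd, tpi, fba, ald, FBPase, tkt1, tkt2, SBPase, rpe,
#' rpi, prk), lower glycolysis towards acetyl-CoA (pgm, eno, pyk, pdh), the
#' phosphoketolase subnetwork (xfpk1, xfpk2, pta), lumped cofactor supply
#' (ATPSyn, NADPase, Supply_Pi) and six irreversible Michaelis-Menten biomass
#' sinks (3PG, GAP, F6P, R5P, PYR, ACCOA). Enzyme promiscuity (FBPase/SBPase,
#' fba/ald, tkt1/tkt2, xfpk1/xfpk2) is encoded as cross-competitive inhibition
#' with binding constants shared with the partner reaction, so a shared
#' constant is counted (and sampled) once.
#'
#' Standard transformed Gibbs energies (kJ/mol, 298.15 K, pH ~7.5) are
#' literature-informed defaults; the two photosystem supply reactions carry
#' strongly negative *effective* values because the photon driving force is
#' lumped into them. Per-metabolite concentration ranges (mM, spanning about
#' two orders of magnitude around literature values) double as the default
#' sampling table. All defaults are overridable through the model file.
#'
#' @return a model definition list; pass to [build_network()] or use
#'   [cbb_model()] directly.
#' @seealso [cbb_model()], [default_ranges()]
#' @export
cbb_definition <- function() {
  met <- function(id, name, role = "balanced", min = NA, max = NA,
                  activity_one = FALSE) {
    m <- list(id = id, name = name, role = role)
    if (!is.na(min)) { m$conc_min <- min; m$conc_max <- max }
    if (activity_one) m$activity_one <- TRUE
    m
  }
  metabolites <- list(
    met("3PG",   "3-phosphoglycerate",            min = 0.5,   max = 20),
    met("BPG",   "1,3-bisphosphoglycerate",       min = 3e-4,  max = 0.03),
    met("GAP",   "glyceraldehyde 3-phosphate",    min = 0.005, max = 0.5),
    met("DHAP",  "dihydroxyacetone phosphate",    min = 0.03,  max = 3),
    met("FBP",   "fructose 1,6-bisphosphate",     min = 0.05,  max = 5),
    met("F6P",   "fructose 6-phosphate",          min = 0.1,   max = 10),
    met("E4P",   "erythrose 4-phosphate",         min = 0.002, max = 0.2),
    met("SBP",   "sedoheptulose 1,7-bisphosphate", min = 0.01, max = 1),
    met("S7P",   "sedoheptulose 7-phosphate",     min = 0.05,  max = 5),
    met("Xu5P",  "xylulose 5-phosphate",          min = 0.02,  max = 2),
    met("R5P",   "ribose 5-phosphate",            min = 0.02,  max = 2),
    met("Ru5P",  "ribulose 5-phosphate",          min = 0.01,  max = 1),
    met("RuBP",  "ribulose 1,5-bisphosphate",     min = 0.02,  max = 2),
    met("2PG",   "2-phosphoglycerate",            min = 0.005, max = 0.5),
    met("PEP",   "phosphoenolpyruvate",           min = 0.01,  max = 1),
    met("PYR",   "pyruvate",                      min = 0.05,  max = 5),
    met("ACCOA", "acetyl-CoA",                    min = 0.01,  max = 1),
    met("ACETP", "acetyl-phosphate",              min = 0.01,  max = 1),
    met("CoA",   "coenzyme A",                    min = 0.05,  max = 5),
    met("Pi",    "inorganic phosphate",           min = 1,     max = 20),
    met("ATP",   "ATP",                           min = 0.5,   max = 10),
    met("ADP",   "ADP",                           min = 0.05,  max = 2),
    met("NADPH", "NADPH",                         min = 0.05,  max = 2),
    met("NADP",  "NADP+",                         min = 0.01,  max = 1),
    met("NAD",   "NAD+",   role = "boundary-unbalanced", min = 0.05,  max = 2),
    met("NADH",  "NADH",   role = "boundary-unbalanced", min = 0.005, max = 0.5),
    met("CO2",   "carbon dioxide", role = "boundary-unbalanced", min = 0.25, max = 0.25),
    met("O2",    "molecular oxygen", role = "boundary-unbalanced", min = 0.23, max = 0.23),
    met("H2O",   "water", role = "boundary-unbalanced", min = 1, max = 1,
        activity_one = TRUE),
    met("PPool", "phosphate pool", role = "phosphate-pool"),
    met("Sink3PG",   "3PG biomass sink pool",   role = "sink-pool"),
    met("SinkGAP",   "GAP biomass sink pool",   role = "sink-pool"),
    met("SinkF6P",   "F6P biomass sink pool",   role = "sink-pool"),
    met("SinkR5P",   "R5P biomass sink pool",   role = "sink-pool"),
    met("SinkPYR",   "PYR biomass sink pool",   role = "sink-pool"),
    met("SinkACCOA", "ACCOA biomass sink pool", role = "sink-pool")
  )

  comp <- function(m) list(metabolite = m, mode = "competitive-inhibitor")
  comp_sh <- function(m, rxn) list(metabolite = m, mode = "competitive-inhibitor",
                                   shared_with = list(reaction = rxn, metabolite = m))
  ainh <- function(m) list(metabolite = m, mode = "allosteric-inhibitor")
  aact <- function(m) list(metabolite = m, mode = "allosteric-activator")
  rx <- function(id, st, law, dG0 = NULL, regulators = NULL, partner = NULL) {
    r <- list(id = id, stoichiometry = st, rate_law = law)
    if (!is.null(dG0)) r$dG0_prime <- dG0
    if (!is.null(regulators)) r$regulators <- regulators
    if (!is.null(partner)) r$promiscuity_partner <- partner
    r
  }

  reactions <- list(
    rx("Rubisco", list(RuBP = -1, CO2 = -1, H2O = -1, `3PG` = 2),
       "reversible-MM", dG0 = -35.0,
       regulators = list(comp("O2"), comp("3PG"), comp("FBP"), comp("SBP"),
                         comp("Pi"), comp("NADPH"))),
    rx("pgk",  list(`3PG` = -1, ATP = -1, BPG = 1, ADP = 1),
       "reversible-MM", dG0 = 18.5),
    rx("gapd", list(BPG = -1, NADPH = -1, GAP = 1, NADP = 1, Pi = 1),
       "reversible-MM", dG0 = -6.3),
    rx("tpi",  list(GAP = -1, DHAP = 1), "reversible-MM", dG0 = -5.5),
    rx("fba",  list(DHAP = -1, GAP = -1, FBP = 1), "reversible-MM", dG0 = -23.8,
       regulators = list(comp_sh("E4P", "ald"), comp_sh("SBP", "ald")),
       partner = "ald"),
    rx("ald",  list(DHAP = -1, E4P = -1, SBP = 1), "reversible-MM", dG0 = -23.8,
       regulators = list(comp_sh("GAP", "fba"), comp_sh("FBP", "fba")),
       partner = "fba"),
    rx("FBPase", list(FBP = -1, H2O = -1, F6P = 1, Pi = 1),
       "irreversible-MM", dG0 = -16.0,
       regulators = list(comp_sh("SBP", "SBPase"), comp("F6P"), comp("Pi"),
                         aact("NADPH")),
       partner = "SBPase"),
    rx("tkt1", list(F6P = -1, GAP = -1, Xu5P = 1, E4P = 1),
       "reversible-MM", dG0 = 4.0,
       regulators = list(comp_sh("S7P", "tkt2"), comp_sh("R5P", "tkt2")),
       partner = "tkt2"),
    rx("tkt2", list(S7P = -1, GAP = -1, Xu5P = 1, R5P = 1),
       "reversible-MM", dG0 = 1.5,
       regulators = list(comp_sh("F6P", "tkt1"), comp_sh("E4P", "tkt1")),
       partner = "tkt1"),
    rx("SBPase", list(SBP = -1, H2O = -1, S7P = 1, Pi = 1),
       "irreversible-MM", dG0 = -16.0,
       regulators = list(comp_sh("FBP", "FBPase"), comp("Pi"), aact("NADPH")),
       partner = "FBPase"),
    rx("rpe",  list(Xu5P = -1, Ru5P = 1), "reversible-MM", dG0 = 0.9),
    rx("rpi",  list(R5P = -1, Ru5P = 1), "reversible-MM", dG0 = 2.0),
    rx("prk",  list(Ru5P = -1, ATP = -1, RuBP = 1, ADP = 1),
       "reversible-MM", dG0 = -21.6,
       regulators = list(comp("ADP"), ainh("3PG"), ainh("Pi"), aact("NADPH"))),
    rx("pgm",  list(`3PG` = -1, `2PG` = 1), "reversible-MM", dG0 = 4.2),
    rx("eno",  list(`2PG` = -1, PEP = 1, H2O = 1), "reversible-MM", dG0 = -4.0),
    rx("pyk",  list(PEP = -1, ADP = -1, PYR = 1, ATP = 1),
       "reversible-MM", dG0 = -27.0,
       regulators = list(ainh("Pi"), ainh("ATP"), aact("FBP"), aact("R5P"))),
    rx("pdh",  list(PYR = -1, CoA = -1, NAD = -1, ACCOA = 1, CO2 = 1, NADH = 1),
       "reversible-MM", dG0 = -33.4,
       regulators = list(ainh("ATP"))),
    rx("xfpk1", list(F6P = -1, Pi = -1, ACETP = 1, E4P = 1, H2O = 1),
       "reversible-MM", dG0 = -52.0,
       regulators = list(comp_sh("Xu5P", "xfpk2"), comp_sh("GAP", "xfpk2"),
                         ainh("PEP")),
       partner = "xfpk2"),
    rx("xfpk2", list(Xu5P = -1, Pi = -1, ACETP = 1, GAP = 1, H2O = 1),
       "reversible-MM", dG0 = -52.0,
       regulators = list(comp_sh("F6P", "xfpk1"), comp_sh("E4P", "xfpk1"),
                         ainh("PEP")),
       partner = "xfpk1"),
    rx("pta",  list(ACETP = -1, CoA = -1, ACCOA = 1, Pi = 1),
       "reversible-MM", dG0 = -9.0,
       regulators = list(ainh("ATP"))),
    rx("ATPSyn",  list(ADP = -1, Pi = -1, ATP = 1, H2O = 1),
       "lumped-supply", dG0 = -35.0),
    rx("NADPase", list(NADP = -1, NADPH = 1), "lumped-supply", dG0 = -35.0),
    rx("Supply_Pi", list(PPool = -1, Pi = 1), "mass-action-symmetric"),
    rx("sink_3PG",   list(`3PG` = -1, Sink3PG = 1),  "irreversible-MM"),
    rx("sink_GAP",   list(GAP = -1, SinkGAP = 1),    "irreversible-MM"),
    rx("sink_F6P",   list(F6P = -1, SinkF6P = 1),    "irreversible-MM"),
    rx("sink_R5P",   list(R5P = -1, SinkR5P = 1),    "irreversible-MM"),
    rx("sink_PYR",   list(PYR = -1, SinkPYR = 1),    "irreversible-MM"),
    rx("sink_ACCOA", list(ACCOA = -1, SinkACCOA = 1, CoA = 1), "irreversible-MM")
  )

  list(
    name = "cbb_synechocystis",
    temperature = 298.15,
    metabolites = metabolites,
    reactions = reactions,
    constraints = list(
      total_cap_mM = 100,
      ppool_multiple = c(1.1, 5),
      ratios = list(
        list(num = "ATP", den = "ADP", min = 1, max = 10),
        list(num = "NADPH", den = "NADP", min = 1, max = 10),
        list(num = "NADH", den = "NAD", min = 0.1, max = 1)
      )
    )
  )
}

#' Build the shipped CBB network model
#'
#' @param source `"shipped"` reads the packaged model file
#'   (`inst/extdata/cbb_synechocystis.model`); `"builtin"` uses the
#'   programmatic definition ([cbb_definition()]). The two are identical
#'   (enforced by the test suite's round-trip check).
#' @return a `cbb_network` object.
#' @examples
#' m <- cbb_model()
#' m$counts$n_reactions   # 29
#' m$counts$n_metabolites # 36
#' m$counts$n_parameters  # 149
#' @export
cbb_model <- function(source = c("shipped", "builtin")) {
  source <- match.arg(source)
  if (source == "builtin") return(build_network(cbb_definition()))
  path <- system.file("extdata", "cbb_synechocystis.model", package = "cbbkin")
  if (!nzchar(path)) return(build_network(cbb_definition()))
  build_network(read_model_definition(path))
}
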