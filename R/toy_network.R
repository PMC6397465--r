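#' Deterministic core-carbon toy network
#'
#' A fixed ~30-reaction model in which bulk acetylation behaves as overflow
#' metabolism: carbon taken up in excess of what biomass synthesis consumes
#' is available to the nuclear acetylation reaction. The network lumps
#' glycolysis, pyruvate oxidation, the TCA cycle, the citrate shuttle,
#' cytosolic ATP-citrate lyase, fatty-acid synthesis, and a biomass reaction
#' consuming amino acids, ATP and lipid. Carbon bookkeeping uses integer
#' "acetyl units" (1 unit = 2 carbons; the toy glucose is C4 = 2 units) so
#' the overflow identity is exact.
#'
#' Designed ground truths (under [toy_baseline_medium()] and the weighted
#' bi-objective after [augment_with_acetylation()]):
#' glucose excess increases acetylation; amino-acid removal increases
#' acetylation; removing every carbon source drives acetylation to 0;
#' deleting the ATP-citrate-lyase gene `ACLY_t` abolishes acetylation;
#' deleting the fatty-acid-synthase gene `FASN_t` increases it.
#'
#' @param augment also add the nuclear acetylation machinery (default TRUE).
#' @return a `metabolic_model`.
#' @export
make_toy_network <- function(augment = TRUE) {
  met <- function(id, name, compartment, formula) {
    data.frame(id = id, name = name, compartment = compartment,
               formula = formula, stringsAsFactors = FALSE)
  }
  mets <- rbind(
    met("glc_e", "glucose (ext)", "e", "C4"),
    met("ac_e", "acetate (ext)", "e", "C2"),
    met("gln_e", "glutamine (ext)", "e", "C2"),
    met("aa_e", "amino acids (ext)", "e", "C2"),
    met("fa_e", "fatty acids (ext)", "e", "C8"),
    met("o2_e", "oxygen (ext)", "e", "O2"),
    met("co2_e", "carbon dioxide (ext)", "e", "CO2"),
    met("glc_c", "glucose", "c", "C4"),
    met("ac_c", "acetate", "c", "C2"),
    met("gln_c", "glutamine", "c", "C2"),
    met("aa_c", "amino-acid pool", "c", "C2"),
    met("fa_c", "fatty acids", "c", "C8"),
    met("pyr_c", "pyruvate", "c", "C2"),
    met("atp_c", "ATP (energy carrier)", "c", "C0"),
    met("accoa_c", "acetyl-CoA", "c", "C2"),
    met("coa_c", "coenzyme A", "c", "C0"),
    met("cit_c", "citrate", "c", "C6"),
    met("oaa_c", "oxaloacetate", "c", "C4"),
    met("lipid_c", "lipid", "c", "C8"),
    met("o2_c", "oxygen", "c", "O2"),
    met("pyr_m", "pyruvate (mito)", "m", "C2"),
    met("accoa_m", "acetyl-CoA (mito)", "m", "C2"),
    met("cit_m", "citrate (mito)", "m", "C6"),
    met("oaa_m", "oxaloacetate (mito)", "m", "C4")
  )

  rx <- function(id, stoich, lb, ub, gene = NA_character_,
                 subsystem = NA_character_) {
    df <- data.frame(id = id, lower_bound = lb, upper_bound = ub,
                     gene_rule = gene, subsystem = subsystem,
                     stringsAsFactors = FALSE)
    df$stoichiometry <- list(stoich)
    df
  }
  ex <- function(met_id) {
    rx(paste0("EX_", met_id), stats::setNames(-1, met_id), 0, 1000,
       subsystem = "exchange")
  }
  rxns <- rbind(
    ex("glc_e"), ex("ac_e"), ex("gln_e"), ex("aa_e"), ex("fa_e"),
    ex("o2_e"), ex("co2_e"),
    rx("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000, "GLUT1_t", "transport"),
    rx("ACt", c(ac_e = -1, ac_c = 1), 0, 1000, "MCT1_t", "transport"),
    rx("GLNt", c(gln_e = -1, gln_c = 1), 0, 1000, "SLC1A5_t", "transport"),
    rx("AAt", c(aa_e = -1, aa_c = 1), 0, 1000, NA, "transport"),
    rx("FAt", c(fa_e = -1, fa_c = 1), 0, 1000, NA, "transport"),
    rx("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, NA, "transport"),
    rx("GLYC", c(glc_c = -1, pyr_c = 2, atp_c = 2), 0, 1000,
       "HK1_t and GAPDH_t", "glycolysis (lumped)"),
    rx("PYRtm", c(pyr_c = -1, pyr_m = 1), 0, 1000,
       "MPC1_t and MPC2_t", "transport"),
    rx("PDHm", c(pyr_m = -1, accoa_m = 1), 0, 1000,
       "PDHA1_t", "pyruvate oxidation"),
    rx("CSm", c(accoa_m = -1, oaa_m = -1, cit_m = 1), 0, 1000,
       "CS_t", "TCA"),
    rx("OXID", c(cit_m = -1, o2_c = -2, oaa_m = 1, co2_e = 2, atp_c = 9),
       0, 1000, "SDHA_t", "TCA oxidation (lumped)"),
    rx("CITtcm", c(cit_m = -1, cit_c = 1), 0, 1000,
       "SLC25A1_t", "citrate shuttle"),
    rx("OAAtmc", c(oaa_c = -1, oaa_m = 1), 0, 1000, NA, "transport"),
    rx("ACLYc", c(cit_c = -1, coa_c = -1, accoa_c = 1, oaa_c = 1), 0, 1000,
       "ACLY_t", "acetyl-CoA synthesis"),
    rx("ACSm", c(ac_c = -1, accoa_m = 1), 0, 1000,
       "ACSS1_t or ACSS2_t", "acetyl-CoA synthesis"),
    rx("FASN", c(accoa_c = -4, lipid_c = 1, coa_c = 4), 0, 1000,
       "FASN_t", "fatty-acid synthesis"),
    rx("FAOX", c(fa_c = -1, accoa_m = 4), 0, 1000,
       "CPT1A_t", "beta-oxidation (lumped)"),
    rx("GLN2AA", c(gln_c = -1, aa_c = 1), 0, 1000,
       "GLS_t", "glutaminolysis (lumped)"),
    rx("BIOMASS", c(aa_c = -2, atp_c = -4, lipid_c = -0.5), 0, 1000,
       NA, "biomass"),
    rx("ATPM", c(atp_c = -1), 0, 1000, NA, "maintenance"),
    rx("DM_lipid_c", c(lipid_c = -1), 0, 1000, NA, "demand")
  )
  model <- metabolic_model(
    metabolites = mets, reactions = rxns,
    compartments = c("e", "c", "m"),
    biomass_reaction_id = "BIOMASS",
    id = "toy_core_carbon"
  )
  if (augment) model <- augment_with_acetylation(model)
  model
}

#' Baseline rich medium for the toy network
#'
#' Uptake allowances (mmol/gDW/h) for the six toy nutrients. Oxygen is
#' non-limiting; fatty acids enter via beta-oxidation, so lipid for biomass
#' always comes through fatty-acid synthase.
#'
#' @return a [medium_spec()].
#' @export
toy_baseline_medium <- function() {
  medium_spec("toy_baseline",
              c(EX_glc_e = 10, EX_ac_e = 2, EX_gln_e = 2,
                EX_aa_e = 4, EX_fa_e = 2, EX_o2_e = 40))
}

#' Toy genes encoding acetyl-CoA synthesis capacity
#'
#' The gene set the expression-cohort generator plants its high/low dichotomy
#' on: the route from carbon sources to nuclear acetyl-CoA (pyruvate
#' dehydrogenase, citrate synthase, the mitochondrial citrate exporter,
#' ATP-citrate lyase, and the acetyl-CoA synthetases).
#'
#' @return character vector of toy gene ids.
#' @export
acetyl_coa_synthesis_genes <- function() {
  c("PDHA1_t", "CS_t", "SLC25A1_t", "ACLY_t", "ACSS1_t", "ACSS2_t")
}

#' Acetyl-unit carbon bookkeeping for a flux state
#'
#' Decomposes carbon flow (in acetyl units, 1 unit = 2 carbons, from
#' metabolite formulas) into: total uptake across exchange reactions, carbon
#' consumed by the biomass reaction, carbon leaving through secretion
#' (CO2 and any other exported species), carbon into non-biomass sinks, and
#' carbon fixed by acetylation. At steady state
#' `uptake = acetylation + biomass + secretion + sinks` exactly.
#'
#' @param model augmented `metabolic_model`.
#' @param result optimal `fba_result` for `model`.
#' @return named list of acetyl-unit rates.
#' @export
acetyl_unit_balance <- function(model, result) {
  stopifnot(result$status == "optimal")
  carbons <- vapply(model$metabolites$formula, function(f) {
    cts <- parse_formula(f)
    if (is.null(cts[["C"]])) 0 else cts[["C"]]
  }, numeric(1))
  names(carbons) <- model$metabolites$id
  units <- carbons / 2
  v <- result$fluxes
  uptake <- 0; secretion <- 0; biomass <- 0; sinks <- 0; acet <- 0
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- r$stoichiometry[[1]]
    # net acetyl-unit creation rate of this reaction; 0 for balanced
    # conversions, nonzero only at system boundaries
    net <- sum(s * units[names(s)]) * v[[r$id]]
    if (abs(net) < 1e-12) next
    if (startsWith(r$id, "EX_")) {
      if (net > 0) uptake <- uptake + net else secretion <- secretion - net
    } else if (r$id == model$biomass_reaction_id) {
      biomass <- biomass - net
    } else if (identical(r$id, "DM_aprotein_n")) {
      acet <- acet - net  # acetyl units fixed on protein leave here
    } else {
      sinks <- sinks - net
    }
  }
  list(uptake = uptake, acetylation = acet, biomass = biomass,
       secretion = secretion, sinks = sinks,
       residual = uptake - acet - biomass - secretion - sinks)
}
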