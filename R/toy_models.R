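# Seeded toy metabolic models exercising the constraint-based pipeline:
# a feasible core network (uptakes, glycolysis-like chain, biomass drain),
# a NAD/purine variant gated by analogues of the seven genes found
# downregulated in NPM1/cohesin-mutant AML, and an IDH-mutant variant
# producing the oncometabolite 2-hydroxyglutarate.
#
# Metabolite formulas use coarse C/N element tags chosen so every internal
# reaction is exactly element-balanced; cofactor detail (phosphate,
# adenine rings) is deliberately collapsed.

# Analogues of the seven genes downregulated in the NPM1/cohesin-mut
# subgroup (ADCY9, DPYSL2, LPL, CHST13, CYP1B1, SLC8A1, SLC1A3).
#' Gene analogues gating the NAD/purine toy subnetwork
#' @return character vector of the seven toy gene ids.
#' @export
nad_purine_gene_set <- function() {
  c("adcy9l", "dpysl2l", "lpll", "chst13l", "cyp1b1l", "slc8a1l", "slc1a3l")
}

#' Build a toy metabolic model
#'
#' @param variant `"core"` (~15-reaction feasible network), `"nad_purine"`
#'   (core plus a nicotinamide/inosine/IMP/lipid subnetwork whose reactions
#'   are gated by [nad_purine_gene_set()] analogues, plus an unrelated
#'   control subnetwork), or `"idh"` (core plus a disabled
#'   akg + NADPH -> 2-HG mutant reaction).
#' @return `metabolic_model`. Reaction `subsystem` tags are `"core"`,
#'   `"nad_purine"`, `"control"` or `"idh"`.
#' @export
build_toy_metabolic_model <- function(variant = c("core", "nad_purine", "idh")) {
  variant <- match.arg(variant)
  mets <- list()  # id, compartment, formula
  rxns <- list()  # id, lb, ub, gpr, subsystem, stoich (named vector)
  add_met <- function(id, comp, formula) {
    mets[[length(mets) + 1L]] <<- list(id = id, compartment = comp,
                                       formula = formula)
  }
  add_rxn <- function(id, stoich, lb, ub, gpr = "", subsystem = "core") {
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr,
                                       subsystem = subsystem)
  }
  # --- core: glucose/glutamine uptake, glycolysis-like chain, TCA-like
  # oxidation, lactate excretion, biomass drain -----------------------------
  add_met("glc_e", "e", "C6");  add_met("glc_c", "c", "C6")
  add_met("pyr_c", "c", "C3");  add_met("lac_c", "c", "C3")
  add_met("lac_e", "e", "C3");  add_met("accoa_c", "c", "C2")
  add_met("co2_c", "c", "C1");  add_met("co2_e", "e", "C1")
  add_met("gln_e", "e", "C5N2"); add_met("gln_c", "c", "C5N2")
  add_met("akg_c", "c", "C5");  add_met("nh4_c", "c", "N1")
  add_met("nh4_e", "e", "N1");  add_met("biomass_c", "c", "C14N2")

  add_rxn("EX_glc", c(glc_e = -1), -10, 0)
  add_rxn("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000, gpr = "glut1")
  add_rxn("GLYCL", c(glc_c = -1, pyr_c = 2), 0, 1000,
          gpr = "gly1 and gly2")
  add_rxn("LDH", c(pyr_c = -1, lac_c = 1), 0, 1000, gpr = "ldha or ldhb")
  add_rxn("LACt", c(lac_c = -1, lac_e = 1), 0, 1000)
  add_rxn("EX_lac", c(lac_e = -1), 0, 1000)
  add_rxn("PDH", c(pyr_c = -1, accoa_c = 1, co2_c = 1), 0, 1000,
          gpr = "pdha1")
  add_rxn("TCAOX", c(accoa_c = -1, co2_c = 2), 0, 1000, gpr = "cs")
  add_rxn("CO2t", c(co2_c = -1, co2_e = 1), 0, 1000)
  add_rxn("EX_co2", c(co2_e = -1), 0, 1000)
  add_rxn("EX_gln", c(gln_e = -1), -5, 0)
  add_rxn("GLNt", c(gln_e = -1, gln_c = 1), 0, 1000, gpr = "slc1a5")
  add_rxn("GLS", c(gln_c = -1, akg_c = 1, nh4_c = 2), 0, 1000, gpr = "gls")
  add_rxn("AKGOX", c(akg_c = -1, co2_c = 5), 0, 1000)
  add_rxn("NH4t", c(nh4_c = -1, nh4_e = 1), 0, 1000)
  add_rxn("EX_nh4", c(nh4_e = -1), 0, 1000)
  add_rxn("BIOMASS", c(pyr_c = -3, gln_c = -1, biomass_c = 1), 0, 1000)
  add_rxn("EX_biomass", c(biomass_c = -1), 0, 1000)

  if (variant == "nad_purine") {
    # NAD arm: nicotinamide import -> NAD synthesis -> export
    add_met("ncam_e", "e", "C6N2"); add_met("ncam_c", "c", "C6N2")
    add_met("nad_c", "c", "C6N2");  add_met("nad_e", "e", "C6N2")
    add_rxn("EX_ncam", c(ncam_e = -1), -5, 0, subsystem = "nad_purine")
    add_rxn("NCAMt", c(ncam_e = -1, ncam_c = 1), 0, 10,
            gpr = "slc1a3l", subsystem = "nad_purine")
    add_rxn("NADSYN", c(ncam_c = -1, nad_c = 1), 0, 10,
            gpr = "adcy9l and cyp1b1l", subsystem = "nad_purine")
    add_rxn("NADex", c(nad_c = -1, nad_e = 1), 0, 1000,
            subsystem = "nad_purine")
    add_rxn("EX_nad", c(nad_e = -1), 0, 1000, subsystem = "nad_purine")
    # purine arm: inosine import -> IMP synthesis -> export
    add_met("ino_e", "e", "C10N4"); add_met("ino_c", "c", "C10N4")
    add_met("imp_c", "c", "C10N4"); add_met("imp_e", "e", "C10N4")
    add_rxn("EX_ino", c(ino_e = -1), -5, 0, subsystem = "nad_purine")
    add_rxn("INOt", c(ino_e = -1, ino_c = 1), 0, 10,
            gpr = "slc8a1l", subsystem = "nad_purine")
    add_rxn("IMPSYN", c(ino_c = -1, imp_c = 1), 0, 10,
            gpr = "dpysl2l", subsystem = "nad_purine")
    add_rxn("IMPex", c(imp_c = -1, imp_e = 1), 0, 10,
            gpr = "chst13l", subsystem = "nad_purine")
    add_rxn("EX_imp", c(imp_e = -1), 0, 1000, subsystem = "nad_purine")
    # lipid arm (LPL analogue): fatty-acid import and modification
    add_met("fa_e", "e", "C16"); add_met("fa_c", "c", "C16")
    add_met("falm_c", "c", "C16"); add_met("falm_e", "e", "C16")
    add_rxn("EX_fa", c(fa_e = -1), -5, 0, subsystem = "nad_purine")
    add_rxn("FAt", c(fa_e = -1, fa_c = 1), 0, 10,
            gpr = "lpll", subsystem = "nad_purine")
    add_rxn("FAMOD", c(fa_c = -1, falm_c = 1), 0, 10,
            gpr = "lpll", subsystem = "nad_purine")
    add_rxn("FALMex", c(falm_c = -1, falm_e = 1), 0, 1000,
            subsystem = "nad_purine")
    add_rxn("EX_falm", c(falm_e = -1), 0, 1000, subsystem = "nad_purine")
    # control subnetwork: serine -> glycine + formate, gated by unrelated
    # genes; flux-isolated from both core and the NAD/purine arms
    add_met("ser_e", "e", "C3N1"); add_met("ser_c", "c", "C3N1")
    add_met("glya_c", "c", "C2N1"); add_met("glya_e", "e", "C2N1")
    add_met("for_c", "c", "C1"); add_met("for_e", "e", "C1")
    add_rxn("EX_ser", c(ser_e = -1), -5, 0, subsystem = "control")
    add_rxn("SERt", c(ser_e = -1, ser_c = 1), 0, 1000,
            gpr = "ctrl_a", subsystem = "control")
    add_rxn("SERCONV", c(ser_c = -1, glya_c = 1, for_c = 1), 0, 1000,
            gpr = "ctrl_b", subsystem = "control")
    add_rxn("GLYAex", c(glya_c = -1, glya_e = 1), 0, 1000,
            gpr = "ctrl_c", subsystem = "control")
    add_rxn("EX_glya", c(glya_e = -1), 0, 1000, subsystem = "control")
    add_rxn("FORex", c(for_c = -1, for_e = 1), 0, 1000,
            subsystem = "control")
    add_rxn("EX_for", c(for_e = -1), 0, 1000, subsystem = "control")
  } else if (variant == "idh") {
    # mutant IDH: akg + NADPH -> 2-HG + NADP, disabled by default
    add_met("nadph_e", "e", "C0"); add_met("nadph_c", "c", "C0")
    add_met("nadp_c", "c", "C0");  add_met("nadp_e", "e", "C0")
    add_met("hg2_c", "c", "C5");   add_met("hg2_e", "e", "C5")
    add_rxn("EX_nadph", c(nadph_e = -1), -5, 0, subsystem = "idh")
    add_rxn("NADPHt", c(nadph_e = -1, nadph_c = 1), 0, 1000,
            subsystem = "idh")
    add_rxn("IDH1MUT", c(akg_c = -1, nadph_c = -1, hg2_c = 1, nadp_c = 1),
            0, 0, gpr = "idh1_r132h", subsystem = "idh")
    add_rxn("NADPt", c(nadp_c = -1, nadp_e = 1), 0, 1000, subsystem = "idh")
    add_rxn("EX_nadp", c(nadp_e = -1), 0, 1000, subsystem = "idh")
    add_rxn("HGt", c(hg2_c = -1, hg2_e = 1), 0, 1000, subsystem = "idh")
    add_rxn("EX_2hg", c(hg2_e = -1), 0, 1000, subsystem = "idh")
  }

  met_df <- do.call(rbind, lapply(mets, function(m)
    data.frame(id = m$id, compartment = m$comp, formula = m$formula,
               stringsAsFactors = FALSE)))
  rxn_df <- do.call(rbind, lapply(rxns, function(r)
    data.frame(id = r$id, lb = r$lb, ub = r$ub, gpr = r$gpr,
               subsystem = r$subsystem, stringsAsFactors = FALSE)))
  S <- matrix(0, nrow(met_df), nrow(rxn_df),
              dimnames = list(met_df$id, rxn_df$id))
  for (r in rxns) S[names(r$stoich), r$id] <- r$stoich
  metabolic_model(paste0("toy_", variant), met_df, rxn_df, S)
}
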