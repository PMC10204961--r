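# Synthetic data generation: a toy central-carbon network of an oleaginous
# yeast (glycolysis, oxidative PPP, phosphoketolase with PTA/ACK arms, TCA
# cycle with glyoxylate shunt, carnitine shuttle, malic enzyme, NADP-GDH
# nitrogen assimilation, ACC/FAS lipid synthesis with 1 ATP + 2 NADPH per
# acetyl unit added, lumped electron transport, SLIME-style lipid pseudo
# reactions) plus condition physiology and MS-level proteomics with a
# heavy-labelled internal standard - all with known ground truth.
#
# Lumping conventions (documented per reaction in the name field where
# non-obvious): protons/water are not balanced; FADH2 is folded into NADH;
# ATP/ADP live in a single cytosolic pool; CO2/O2 live in single pools;
# the glyoxylate-shunt transport steps are folded into ICL.

#' Build a toy central-carbon metabolic model
#'
#' Generates a ~60-reaction (glucose/acetate) or ~68-reaction (xylose)
#' network reproducing the topological motifs of oleaginous-yeast central
#' metabolism with a protein/lipid/carbohydrate biomass equation. The
#' xylose variant carries xylose reductase, xylitol dehydrogenase and
#' xylulokinase plus (optionally) the D-arabinitol bypass of xylulokinase:
#' D-arabinitol 4-dehydrogenase, D-arabinitol 2-dehydrogenase (NADP by
#' default) and D-ribulokinase.
#'
#' @param variant `"glucose"`, `"xylose"` or `"acetate"`; opens the matching
#'   substrate exchange.
#' @param include_xpk include the phosphoketolase/PTA route (default TRUE).
#' @param include_dad_bypass include the D-arabinitol bypass (default TRUE
#'   for the xylose variant, FALSE otherwise).
#' @param uptake substrate uptake bound, mmol/gDCW/h.
#' @param gam growth-associated maintenance in the initial biomass equation,
#'   mmol ATP/gDCW.
#' @return a validated `metabolic_model` with enzyme annotations.
#' @export
make_toy_network <- function(variant = c("glucose", "xylose", "acetate"),
                             include_xpk = TRUE,
                             include_dad_bypass = (variant == "xylose"),
                             uptake = 10, gam = 120) {
  variant <- match.arg(variant)
  force(include_dad_bypass)

  met <- function(id, name, comp) {
    data.frame(id = id, name = name, compartment = comp,
               formula = NA_character_, charge = NA_real_,
               stringsAsFactors = FALSE)
  }
  mets <- list(
    met("glc_c", "D-glucose", "c"), met("g6p_c", "glucose 6-phosphate", "c"),
    met("f6p_c", "fructose 6-phosphate", "c"),
    met("fdp_c", "fructose 1,6-bisphosphate", "c"),
    met("dhap_c", "dihydroxyacetone phosphate", "c"),
    met("g3p_c", "glyceraldehyde 3-phosphate", "c"),
    met("pg3_c", "3-phosphoglycerate", "c"),
    met("pep_c", "phosphoenolpyruvate", "c"),
    met("pyr_c", "pyruvate", "c"),
    met("pg6_c", "6-phospho-D-gluconate", "c"),
    met("ru5p_c", "D-ribulose 5-phosphate", "c"),
    met("xu5p_c", "D-xylulose 5-phosphate", "c"),
    met("r5p_c", "D-ribose 5-phosphate", "c"),
    met("acp_c", "acetyl phosphate", "c"),
    met("ac_c", "acetate", "c"),
    met("acald_c", "acetaldehyde", "c"),
    met("accoa_c", "acetyl-CoA", "c"),
    met("malcoa_c", "malonyl-CoA", "c"),
    met("cit_c", "citrate", "c"), met("oaa_c", "oxaloacetate", "c"),
    met("mal_c", "(S)-malate", "c"), met("glx_c", "glyoxylate", "c"),
    met("akg_c", "2-oxoglutarate", "c"), met("glu_c", "L-glutamate", "c"),
    met("nh4_c", "ammonium", "c"),
    met("glyc3p_c", "glycerol 3-phosphate", "c"),
    met("c160_c", "palmitate (C16:0)", "c"),
    met("c180_c", "stearate (C18:0)", "c"),
    met("c181_c", "oleate (C18:1)", "c"),
    met("atp_c", "ATP", "c"), met("adp_c", "ADP", "c"),
    met("nad_c", "NAD+", "c"), met("nadh_c", "NADH", "c"),
    met("nadp_c", "NADP+", "c"), met("nadph_c", "NADPH", "c"),
    met("o2_c", "oxygen", "c"), met("co2_c", "carbon dioxide", "c"),
    met("pyr_m", "pyruvate", "m"), met("accoa_m", "acetyl-CoA", "m"),
    met("oaa_m", "oxaloacetate", "m"), met("cit_m", "citrate", "m"),
    met("icit_m", "isocitrate", "m"), met("akg_m", "2-oxoglutarate", "m"),
    met("succ_m", "succinate", "m"), met("fum_m", "fumarate", "m"),
    met("mal_m", "(S)-malate", "m"),
    met("nad_m", "NAD+", "m"), met("nadh_m", "NADH", "m"),
    met("protein_c", "protein pseudo-component (1 g/mmol)", "c"),
    met("lipid_c", "lipid pseudo-component (1 g/mmol)", "c"),
    met("carb_c", "carbohydrate pseudo-component (1 g/mmol)", "c"),
    met("backbone_c", "lipid backbone mass (g)", "c"),
    met("acyl_C160_c", "acyl-chain mass C16:0 (g)", "c"),
    met("acyl_C180_c", "acyl-chain mass C18:0 (g)", "c"),
    met("acyl_C181_c", "acyl-chain mass C18:1 (g)", "c"),
    met("biomass_c", "biomass (1 g/mmol)", "c"))
  if (variant == "xylose") {
    mets <- c(mets, list(
      met("xyl_c", "D-xylose", "c"), met("xylt_c", "xylitol", "c"),
      met("xlu_c", "D-xylulose", "c")))
    if (include_dad_bypass) {
      mets <- c(mets, list(met("abt_c", "D-arabinitol", "c"),
                           met("rbl_c", "D-ribulose", "c")))
    }
  }
  metabolites <- do.call(rbind, mets)

  R <- new_reaction  # terseness
  iso <- function(...) lapply(list(...), identity)
  rx <- list()
  add <- function(r) rx[[r$id]] <<- r

  # exchanges (uptake negative)
  add(R("EX_glc", c(glc_c = -1), lb = if (variant == "glucose") -uptake else 0,
        ub = 0, name = "D-glucose exchange", subsystem = "exchange"))
  if (variant == "xylose") {
    add(R("EX_xyl", c(xyl_c = -1), lb = -uptake, ub = 0,
          name = "D-xylose exchange", subsystem = "exchange"))
    add(R("EX_xylt", c(xylt_c = -1), lb = 0, ub = DEFAULT_BOUND,
          name = "xylitol exchange (secretion)", subsystem = "exchange"))
  }
  add(R("EX_ac", c(ac_c = -1), lb = if (variant == "acetate") -uptake else 0,
        ub = DEFAULT_BOUND, name = "acetate exchange",
        subsystem = "exchange"))
  add(R("EX_o2", c(o2_c = -1), lb = -DEFAULT_BOUND, ub = 0,
        name = "oxygen exchange", subsystem = "exchange"))
  add(R("EX_co2", c(co2_c = -1), lb = 0, ub = DEFAULT_BOUND,
        name = "carbon dioxide exchange", subsystem = "exchange"))
  add(R("EX_nh4", c(nh4_c = -1), lb = -DEFAULT_BOUND, ub = 0,
        name = "ammonium exchange", subsystem = "exchange"))
  add(R("EX_biomass", c(biomass_c = -1), lb = 0, ub = DEFAULT_BOUND,
        name = "biomass sink", subsystem = "exchange"))

  # glycolysis / gluconeogenesis
  add(R("HXK", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), lb = 0,
        name = "hexokinase", gene_rule = iso("E_HXK"),
        subsystem = "glycolysis"))
  add(R("PGI", c(g6p_c = -1, f6p_c = 1),
        name = "glucose-6-phosphate isomerase", gene_rule = iso("E_PGI"),
        subsystem = "glycolysis"))
  add(R("PFK", c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1), lb = 0,
        name = "phosphofructokinase", gene_rule = iso("E_PFK"),
        subsystem = "glycolysis"))
  add(R("FBP", c(fdp_c = -1, f6p_c = 1), lb = 0,
        name = "fructose-bisphosphatase", gene_rule = iso("E_FBP"),
        subsystem = "gluconeogenesis"))
  add(R("ALD", c(fdp_c = -1, dhap_c = 1, g3p_c = 1),
        name = "fructose-bisphosphate aldolase", gene_rule = iso("E_ALD"),
        subsystem = "glycolysis"))
  add(R("TPI", c(dhap_c = -1, g3p_c = 1),
        name = "triose-phosphate isomerase", gene_rule = iso("E_TPI"),
        subsystem = "glycolysis"))
  add(R("GAPD", c(g3p_c = -1, nad_c = -1, adp_c = -1, pg3_c = 1,
                  nadh_c = 1, atp_c = 1),
        name = "GAPDH + phosphoglycerate kinase (lumped)",
        gene_rule = iso("E_GAPD"), subsystem = "glycolysis"))
  add(R("ENO", c(pg3_c = -1, pep_c = 1),
        name = "phosphoglycerate mutase + enolase (lumped)",
        gene_rule = iso("E_ENO"), subsystem = "glycolysis"))
  add(R("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), lb = 0,
        name = "pyruvate kinase", gene_rule = iso("E_PYK"),
        subsystem = "glycolysis"))
  add(R("PEPCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1),
        lb = 0, name = "PEP carboxykinase", gene_rule = iso("E_PEPCK"),
        subsystem = "gluconeogenesis"))

  # oxidative + non-oxidative PPP
  add(R("ZWF", c(g6p_c = -1, nadp_c = -1, pg6_c = 1, nadph_c = 1), lb = 0,
        name = "glucose-6-phosphate dehydrogenase (+lactonase, lumped)",
        gene_rule = iso("E_ZWF"), subsystem = "oxPPP"))
  add(R("GND", c(pg6_c = -1, nadp_c = -1, ru5p_c = 1, co2_c = 1,
                 nadph_c = 1), lb = 0,
        name = "6-phosphogluconate dehydrogenase", gene_rule = iso("E_GND"),
        subsystem = "oxPPP"))
  add(R("RPE", c(ru5p_c = -1, xu5p_c = 1),
        name = "ribulose-phosphate 3-epimerase", gene_rule = iso("E_RPE"),
        subsystem = "PPP"))
  add(R("RPI", c(ru5p_c = -1, r5p_c = 1),
        name = "ribose-5-phosphate isomerase", gene_rule = iso("E_RPI"),
        subsystem = "PPP"))
  add(R("NONOX", c(xu5p_c = -2, r5p_c = -1, f6p_c = 2, g3p_c = 1),
        name = "non-oxidative PPP (transketolase/transaldolase, lumped)",
        gene_rule = iso("E_TKT1", "E_TKT2"), subsystem = "PPP"))

  # phosphoketolase arm + acetate assimilation
  if (include_xpk) {
    add(R("XPK", c(xu5p_c = -1, acp_c = 1, g3p_c = 1), lb = 0,
          name = "phosphoketolase", gene_rule = iso("E_XPK"),
          subsystem = "XPK pathway"))
    add(R("PTA", c(acp_c = -1, accoa_c = 1), lb = 0,
          name = "phosphotransacetylase (CoA/Pi lumped)",
          gene_rule = iso("E_PTA"), subsystem = "XPK pathway"))
  }
  add(R("ACS", c(ac_c = -1, atp_c = -2, accoa_c = 1, adp_c = 2), lb = 0,
        name = "acetyl-CoA synthetase (AMP cost as 2 ATP)",
        gene_rule = iso("E_ACS"), subsystem = "acetate assimilation"))

  # pyruvate decarboxylase bypass to cytosolic acetyl-CoA
  add(R("PDC", c(pyr_c = -1, acald_c = 1, co2_c = 1), lb = 0,
        name = "pyruvate decarboxylase", gene_rule = iso("E_PDC"),
        subsystem = "pyruvate metabolism"))
  add(R("ALDD", c(acald_c = -1, nadp_c = -1, ac_c = 1, nadph_c = 1), lb = 0,
        name = "acetaldehyde dehydrogenase (NADP)",
        gene_rule = iso("E_ALDD"), subsystem = "pyruvate metabolism"))

  # ATP-citrate lyase route
  add(R("CTPt", c(cit_m = -1, cit_c = 1),
        name = "citrate carrier", gene_rule = iso("E_CTP"),
        subsystem = "transport"))
  add(R("ACL", c(cit_c = -1, atp_c = -1, accoa_c = 1, oaa_c = 1, adp_c = 1),
        lb = 0, name = "ATP-citrate lyase", gene_rule = iso("E_ACL"),
        subsystem = "acetyl-CoA metabolism"))

  # mitochondria: PDH, TCA, shuttles
  add(R("PYRtm", c(pyr_c = -1, pyr_m = 1), lb = 0,
        name = "pyruvate mitochondrial transport", subsystem = "transport"))
  add(R("PDH", c(pyr_m = -1, nad_m = -1, accoa_m = 1, nadh_m = 1,
                 co2_c = 1), lb = 0,
        name = "pyruvate dehydrogenase complex",
        gene_rule = list(c("E_PDH1", "E_PDH2")),
        subsystem = "pyruvate metabolism"))
  add(R("CS", c(accoa_m = -1, oaa_m = -1, cit_m = 1), lb = 0,
        name = "citrate synthase", gene_rule = iso("E_CS"),
        subsystem = "TCA cycle"))
  add(R("ACO", c(cit_m = -1, icit_m = 1),
        name = "aconitase", gene_rule = iso("E_ACO"),
        subsystem = "TCA cycle"))
  add(R("IDH", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_c = 1,
                 nadh_m = 1), lb = 0,
        name = "isocitrate dehydrogenase (NAD)", gene_rule = iso("E_IDH"),
        subsystem = "TCA cycle"))
  add(R("AKGDH", c(akg_m = -1, nad_m = -1, adp_c = -1, succ_m = 1,
                   co2_c = 1, nadh_m = 1, atp_c = 1), lb = 0,
        name = "2-oxoglutarate dehydrogenase + succinyl-CoA synthetase",
        gene_rule = iso("E_AKGDH"), subsystem = "TCA cycle"))
  add(R("SDH", c(succ_m = -1, nad_m = -1, fum_m = 1, nadh_m = 1), lb = 0,
        name = "succinate dehydrogenase (FADH2 folded into NADH)",
        gene_rule = iso("E_SDH"), subsystem = "TCA cycle"))
  add(R("FUM", c(fum_m = -1, mal_m = 1),
        name = "fumarase", gene_rule = iso("E_FUM"),
        subsystem = "TCA cycle"))
  add(R("MDH1", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1),
        name = "malate dehydrogenase (mitochondrial)",
        gene_rule = iso("E_MDH1"), subsystem = "TCA cycle"))
  add(R("MALtm", c(mal_c = -1, mal_m = 1),
        name = "malate mitochondrial transport", subsystem = "transport"))
  add(R("AKGtm", c(akg_m = -1, akg_c = 1),
        name = "2-oxoglutarate mitochondrial transport",
        subsystem = "transport"))
  add(R("CRC", c(accoa_c = -1, accoa_m = 1), lb = 0,
        name = "carnitine acetyltransferase shuttle (lumped)",
        gene_rule = iso("E_CRC"), subsystem = "transport"))

  # glyoxylate shunt (transport steps folded into ICL)
  add(R("ICL", c(icit_m = -1, glx_c = 1, succ_m = 1), lb = 0,
        name = "isocitrate lyase (with transport, lumped)",
        gene_rule = iso("E_ICL"), subsystem = "glyoxylate shunt"))
  add(R("MLS", c(glx_c = -1, accoa_c = -1, mal_c = 1), lb = 0,
        name = "malate synthase", gene_rule = iso("E_MLS"),
        subsystem = "glyoxylate shunt"))

  # cytosolic redox and anaplerosis
  add(R("MDH2", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
        name = "malate dehydrogenase (cytosolic)",
        gene_rule = iso("E_MDH2"), subsystem = "gluconeogenesis"))
  add(R("ME", c(mal_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1,
                nadph_c = 1), lb = 0,
        name = "malic enzyme (NADP)", gene_rule = iso("E_ME"),
        subsystem = "pyruvate metabolism"))

  # nitrogen assimilation and protein synthesis
  add(R("GDH1", c(akg_c = -1, nh4_c = -1, nadph_c = -1, glu_c = 1,
                  nadp_c = 1), lb = 0,
        name = "glutamate dehydrogenase (NADP)", gene_rule = iso("E_GDH1"),
        subsystem = "nitrogen assimilation"))
  add(R("PROT_SYN", c(glu_c = -9.09, atp_c = -39.1, protein_c = 1,
                      adp_c = 39.1), lb = 0,
        name = "protein synthesis pseudo-reaction (9.09 mmol AA/g, 4.3 ATP/AA)",
        subsystem = "biomass"))

  # lipid synthesis: ACC + FAS cost 1 ATP + 2 NADPH per acetyl unit added
  add(R("G3PD", c(dhap_c = -1, nadh_c = -1, glyc3p_c = 1, nad_c = 1), lb = 0,
        name = "glycerol-3-phosphate dehydrogenase",
        gene_rule = iso("E_G3PD"), subsystem = "lipid synthesis"))
  add(R("ACC", c(accoa_c = -1, atp_c = -1, co2_c = -1, malcoa_c = 1,
                 adp_c = 1), lb = 0,
        name = "acetyl-CoA carboxylase", gene_rule = iso("E_ACC"),
        subsystem = "lipid synthesis"))
  add(R("FAS", c(accoa_c = -1, malcoa_c = -7, nadph_c = -14, c160_c = 1,
                 nadp_c = 14, co2_c = 7), lb = 0,
        name = "fatty acid synthase (C16:0)",
        gene_rule = list(c("E_FAS1", "E_FAS2")),
        subsystem = "lipid synthesis"))
  add(R("ELO", c(c160_c = -1, malcoa_c = -1, nadph_c = -2, c180_c = 1,
                 nadp_c = 2, co2_c = 1), lb = 0,
        name = "fatty acid elongase (C16->C18)", gene_rule = iso("E_ELO"),
        subsystem = "lipid synthesis"))
  add(R("DES1", c(c180_c = -1, nadh_c = -1, o2_c = -0.5, c181_c = 1,
                  nad_c = 1), lb = 0,
        name = "stearoyl desaturase", gene_rule = iso("E_DES1"),
        subsystem = "lipid synthesis"))
  add(R("ACYL160", c(c160_c = -1, acyl_C160_c = 0.25643), lb = 0,
        name = "C16:0 chain mass pseudo-reaction", subsystem = "SLIME"))
  add(R("ACYL180", c(c180_c = -1, acyl_C180_c = 0.28448), lb = 0,
        name = "C18:0 chain mass pseudo-reaction", subsystem = "SLIME"))
  add(R("ACYL181", c(c181_c = -1, acyl_C181_c = 0.28246), lb = 0,
        name = "C18:1 chain mass pseudo-reaction", subsystem = "SLIME"))
  add(R("BACKBONE", c(glyc3p_c = -1, backbone_c = 0.041), lb = 0,
        name = "lipid backbone mass pseudo-reaction", subsystem = "SLIME"))
  add(R("LIPID_SYN", c(backbone_c = -0.10, acyl_C160_c = -0.27,
                       acyl_C180_c = -0.09, acyl_C181_c = -0.54,
                       lipid_c = 1), lb = 0,
        name = "SLIME lipid merge (mass fractions)", subsystem = "SLIME"))

  # carbohydrate, biomass, energy
  add(R("CARB_SYN", c(g6p_c = -6.17, atp_c = -6.17, carb_c = 1,
                      adp_c = 6.17), lb = 0,
        name = "carbohydrate synthesis pseudo-reaction (glucan, 162 g/mol)",
        subsystem = "biomass"))
  add(R("BIOMASS", c(protein_c = -0.45, lipid_c = -0.10, carb_c = -0.45,
                     atp_c = -gam, adp_c = gam, biomass_c = 1), lb = 0,
        name = "biomass assembly (1 g/mmol)", subsystem = "biomass"))
  add(R("NGAM", c(atp_c = -1, adp_c = 1), lb = 0,
        name = "non-growth ATP maintenance", subsystem = "energy"))
  add(R("ETC", c(nadh_m = -1, o2_c = -0.5, adp_c = -1.5, nad_m = 1,
                 atp_c = 1.5), lb = 0,
        name = "oxidative phosphorylation (lumped, P/O 1.5)",
        gene_rule = iso("E_ETC"), subsystem = "energy"))
  add(R("NDE", c(nadh_c = -1, o2_c = -0.5, adp_c = -0.9, nad_c = 1,
                 atp_c = 0.9), lb = 0,
        name = "external NADH dehydrogenase (lumped, P/O 0.9)",
        gene_rule = iso("E_NDE"), subsystem = "energy"))

  # xylose assimilation
  if (variant == "xylose") {
    add(R("XR", c(xyl_c = -1, nadph_c = -1, xylt_c = 1, nadp_c = 1), lb = 0,
          name = "xylose reductase (NADPH)", gene_rule = iso("E_XR"),
          subsystem = "xylose assimilation"))
    add(R("XDH", c(xylt_c = -1, nad_c = -1, xlu_c = 1, nadh_c = 1), lb = 0,
          name = "xylitol dehydrogenase", gene_rule = iso("E_XDH"),
          subsystem = "xylose assimilation"))
    add(R("XK", c(xlu_c = -1, atp_c = -1, xu5p_c = 1, adp_c = 1), lb = 0,
          name = "xylulokinase", gene_rule = iso("E_XK"),
          subsystem = "xylose assimilation"))
    if (include_dad_bypass) {
      add(R("DAD4", c(xlu_c = -1, nadh_c = -1, abt_c = 1, nad_c = 1), lb = 0,
            name = "D-arabinitol 4-dehydrogenase (reduction direction)",
            gene_rule = iso("E_DAD4"), subsystem = "xylose assimilation"))
      add(R("DAD2", c(abt_c = -1, nadp_c = -1, rbl_c = 1, nadph_c = 1),
            lb = 0,
            name = "D-arabinitol 2-dehydrogenase / LXR (NADP)",
            gene_rule = iso("E_DAD2"), subsystem = "xylose assimilation"))
      add(R("RK", c(rbl_c = -1, atp_c = -1, ru5p_c = 1, adp_c = 1), lb = 0,
            name = "D-ribulokinase", gene_rule = iso("E_RK"),
            subsystem = "xylose assimilation"))
    }
  }

  new_model(paste0("toy_", variant),
            c(c = "cytosol", m = "mitochondria"),
            metabolites, rx, enzymes = toy_enzyme_table(),
            objective = "BIOMASS")
}

# enzyme annotation table: id, gene(s), MW (g/mmol), EC number(s)
toy_enzyme_table <- function() {
  e <- function(id, mw, ec) data.frame(id = id, genes = id, mw = mw, ec = ec,
                                       stringsAsFactors = FALSE)
  do.call(rbind, list(
    e("E_HXK", 54, "2.7.1.1"), e("E_PGI", 61, "5.3.1.9"),
    e("E_PFK", 93, "2.7.1.11"), e("E_FBP", 38, "3.1.3.11"),
    e("E_ALD", 40, "4.1.2.13"), e("E_TPI", 27, "5.3.1.1"),
    e("E_GAPD", 36, "1.2.1.12"), e("E_ENO", 47, "4.2.1.11"),
    e("E_PYK", 55, "2.7.1.40"), e("E_PEPCK", 61, "4.1.1.49"),
    e("E_ZWF", 59, "1.1.1.49"), e("E_GND", 54, "1.1.1.44"),
    e("E_RPE", 25, "5.1.3.1"), e("E_RPI", 29, "5.3.1.6"),
    e("E_TKT1", 74, "2.2.1.1"), e("E_TKT2", 75, "2.2.1.1"),
    e("E_XPK", 92, "4.1.2.9"), e("E_PTA", 36, "2.3.1.8"),
    e("E_ACK", 44, "2.7.2.1"), e("E_ACS", 73, "6.2.1.1"),
    e("E_PDC", 61, "4.1.1.1"), e("E_ALDD", 54, "1.2.1.4"),
    e("E_ACL", 120, "2.3.3.8"), e("E_CTP", 33, "2.A.1.1"),
    e("E_PDH1", 44, "1.2.4.1"), e("E_PDH2", 39, "1.2.4.1"),
    e("E_CS", 52, "2.3.3.1"), e("E_ACO", 85, "4.2.1.3"),
    e("E_IDH", 40, "1.1.1.41"), e("E_AKGDH", 114, "1.2.4.2"),
    e("E_SDH", 70, "1.3.5.1"), e("E_FUM", 53, "4.2.1.2"),
    e("E_MDH1", 35, "1.1.1.37"), e("E_MDH2", 36, "1.1.1.37"),
    e("E_ME", 62, "1.1.1.40"), e("E_ICL", 60, "4.1.3.1"),
    e("E_MLS", 63, "2.3.3.9"), e("E_CRC", 67, "2.3.1.7"),
    e("E_GDH1", 50, "1.4.1.4"), e("E_G3PD", 43, "1.1.1.8"),
    e("E_ACC", 250, "6.4.1.2"), e("E_FAS1", 230, "2.3.1.86"),
    e("E_FAS2", 210, "2.3.1.86"), e("E_ELO", 39, "2.3.1.199"),
    e("E_DES1", 51, "1.14.19.1"), e("E_ETC", 200, "7.1.1.2"),
    e("E_NDE", 62, "1.6.5.9"), e("E_XR", 36, "1.1.1.307"),
    e("E_XDH", 38, "1.1.1.9"), e("E_XK", 68, "2.7.1.17"),
    e("E_DAD4", 42, "1.1.1.11"), e("E_DAD2", 29, "1.1.1.10"),
    e("E_RK", 55, "2.7.1.16")))
}

# planted "true" turnover numbers (1/s) used by the generator
toy_true_kcats <- function() {
  c(E_HXK = 150, E_PGI = 400, E_PFK = 120, E_FBP = 20, E_ALD = 80,
    E_TPI = 3000, E_GAPD = 200, E_ENO = 180, E_PYK = 300, E_PEPCK = 38,
    E_ZWF = 180, E_GND = 90, E_RPE = 400, E_RPI = 350, E_TKT1 = 100,
    E_TKT2 = 60, E_XPK = 50, E_PTA = 250, E_ACK = 310, E_ACS = 25,
    E_PDC = 100, E_ALDD = 30, E_ACL = 35, E_CTP = 90, E_PDH1 = 486,
    E_PDH2 = 486, E_CS = 540, E_ACO = 120, E_IDH = 60, E_AKGDH = 80,
    E_SDH = 100, E_FUM = 800, E_MDH1 = 900, E_MDH2 = 500, E_ME = 55,
    E_ICL = 40, E_MLS = 45, E_CRC = 130, E_GDH1 = 95, E_G3PD = 160,
    E_ACC = 10, E_FAS1 = 5, E_FAS2 = 5, E_ELO = 8, E_DES1 = 12,
    E_ETC = 150, E_NDE = 120, E_XR = 18, E_XDH = 22, E_XK = 35,
    E_DAD4 = 28, E_DAD2 = 26, E_RK = 35)
}

TOY_ORGANISM <- "Rhodotorula toruloides"

#' Synthetic kcat database for the toy network
#'
#' One exact record (matching EC number, substrate and organism) per enzyme
#' at the planted true kcat, plus decoy records at looser match levels with
#' different values, so the stepwise relaxation of the matcher is exercised:
#' some enzymes only carry cross-organism or cross-substrate records.
#'
#' @param model a toy `metabolic_model` (defines enzymes and substrate
#'   names).
#' @param seed integer seed for the decoys.
#' @return data.frame with columns `ec_number`, `substrate`, `organism`,
#'   `kcat_per_s`, `source`.
#' @export
make_toy_kcat_db <- function(model, seed = 1) {
  set.seed(seed)
  true_k <- toy_true_kcats()
  enz <- model$enzymes
  met_name <- setNames(model$metabolites$name, model$metabolites$id)
  # primary substrate of the first reaction each enzyme catalyses
  sub_of <- list()
  for (r in model$reactions) {
    for (isoz in r$gene_rule) for (e in isoz) {
      if (is.null(sub_of[[e]])) {
        subs <- names(r$stoich)[r$stoich < 0]
        cof <- grepl("^(atp|adp|nad|nadh|nadp|nadph|o2|co2)_", subs)
        pick <- if (any(!cof)) subs[!cof][1] else subs[1]
        sub_of[[e]] <- tolower(met_name[[pick]])
      }
    }
  }
  # a few enzymes deliberately lack exact records (relaxation levels 2-4)
  only_level2 <- c("E_FBP", "E_DAD2")   # other organism, same substrate
  only_level3 <- c("E_ICL")             # same organism, other substrate
  only_level4 <- c("E_ELO")             # neither
  rows <- list()
  addr <- function(ec, sub, org, k, src) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ec_number = ec, substrate = sub, organism = org, kcat_per_s = k,
      source = src, stringsAsFactors = FALSE)
  }
  for (e in names(sub_of)) {
    if (!e %in% enz$id) next
    ec <- strsplit(enz$ec[match(e, enz$id)], ";")[[1]][1]
    k <- true_k[[e]]
    sub <- sub_of[[e]]
    if (e %in% only_level2) {
      addr(ec, sub, "Saccharomyces cerevisiae", k, "synthetic-l2")
    } else if (e %in% only_level3) {
      addr(ec, "unrelated substrate", TOY_ORGANISM, k, "synthetic-l3")
    } else if (e %in% only_level4) {
      addr(ec, "unrelated substrate", "Escherichia coli", k, "synthetic-l4")
    } else {
      addr(ec, sub, TOY_ORGANISM, k, "synthetic-exact")
      # decoys that must lose against the exact record
      addr(ec, sub, "Saccharomyces cerevisiae",
           k * runif(1, 1.5, 4), "synthetic-decoy")
      addr(ec, "unrelated substrate", "Escherichia coli",
           k * runif(1, 2, 8), "synthetic-decoy")
    }
  }
  do.call(rbind, rows)
}

#' Simulate a cultivation condition with known ground truth
#'
#' Builds the enzyme-constrained version of the toy model with the planted
#' true kcats, fixes the biomass composition of the requested phase,
#' maximizes growth and makes the solution parsimonious; the resulting flux
#' vector, enzyme usages and exchange rates are the ground truth. Measured
#' physiology is emitted with multiplicative lognormal noise at `rate_cv`
#' (`rate_cv = 0` reproduces the truth exactly). The nitrogen-limited phase
#' lowers the protein coefficient and raises the lipid coefficient of the
#' biomass equation.
#'
#' @param model a toy `metabolic_model` from [make_toy_network()].
#' @param phase `"exp"` (nutrient excess) or `"Nlim"` (nitrogen limited).
#' @param uptake substrate uptake rate, mmol/gDCW/h.
#' @param ngam non-growth maintenance, mmol ATP/gDCW/h.
#' @param rate_cv coefficient of variation of measured rates.
#' @param seed integer seed.
#' @param sigma,f_assumed pool parameters of the truth EC model.
#' @return list with `physiology` (a `physiology_data`) and `truth` (list:
#'   `ec_model`, `flux`, `net_flux`, `E` mmol/gDCW, `kcats`, `composition`,
#'   `mu`, `rates`).
#' @export
simulate_condition <- function(model, phase = c("exp", "Nlim"), uptake = 10,
                               ngam = 1.5, rate_cv = 0, seed = 1,
                               sigma = 0.35, f_assumed = 0.5) {
  phase <- match.arg(phase)
  set.seed(seed)
  comp <- if (phase == "exp") {
    biomass_composition(protein = 0.45, lipid = 0.10,
                        acyl_profile = c("C16:0" = 0.30, "C18:0" = 0.10,
                                         "C18:1" = 0.60))
  } else {
    biomass_composition(protein = 0.16, lipid = 0.34,
                        acyl_profile = c("C16:0" = 0.25, "C18:0" = 0.10,
                                         "C18:1" = 0.65))
  }
  model <- rescale_biomass(model, comp)
  model$reactions$NGAM$lb <- ngam
  # true EC model with planted kcats
  irr <- expand_isozymes(split_reversible(model))
  true_k <- toy_true_kcats()
  asg <- list()
  for (r in irr$reactions) {
    for (isoz in r$gene_rule) for (e in isoz) {
      asg[[length(asg) + 1L]] <- data.frame(
        reaction = r$id, enzyme = e, kcat = true_k[[e]], level = 1L,
        stringsAsFactors = FALSE)
    }
  }
  ec <- build_ec_model(irr, do.call(rbind, asg), sigma = sigma,
                       f = f_assumed, Ptot = comp$protein)
  sol <- fba(ec)
  if (sol$status != "optimal") {
    stop("toy condition infeasible; cannot simulate", call. = FALSE)
  }
  mu <- sol$objective_value
  # parsimonious refinement at the growth optimum
  all_ones <- setNames(rep(1, length(ec$reactions)), names(ec$reactions))
  pars <- optimize_flux(ec, all_ones, maximize = FALSE,
                        extra_row = setNames(1, ec$objective),
                        extra_lb = mu * (1 - 1e-9), extra_ub = mu)
  flux <- if (pars$status == "optimal") pars$x else sol$flux
  net <- map_to_base(flux, ec)
  used <- ec$annotations$ec$enzymes
  E <- setNames(vapply(used, function(e)
    flux[[paste0(DRAW_PREFIX, e)]], 0), used)
  noisy <- function(x) {
    if (rate_cv <= 0) return(x)
    x * rlnorm(length(x), -0.5 * log(1 + rate_cv^2),
               sqrt(log(1 + rate_cv^2)))
  }
  sub_ex <- switch(model$id, toy_glucose = "EX_glc", toy_xylose = "EX_xyl",
                   toy_acetate = "EX_ac", "EX_glc")
  rates <- list(mu = mu, uptake = abs(net[[sub_ex]]),
                co2 = abs(net[["EX_co2"]]), o2 = abs(net[["EX_o2"]]))
  byp <- character()
  if ("EX_xylt" %in% names(net) && net[["EX_xylt"]] > 1e-6) {
    byp <- c(byp, EX_xylt = net[["EX_xylt"]])
  }
  phys <- physiology_data(
    mu = noisy(rates$mu),
    uptake = setNames(noisy(rates$uptake), sub_ex),
    co2 = noisy(rates$co2), o2 = noisy(rates$o2),
    byproducts = if (length(byp)) noisy(byp) else numeric(),
    Ptot = noisy(comp$protein), Ptot_sd = comp$protein * rate_cv,
    lipid = noisy(comp$lipid), acyl_profile = comp$acyl_profile,
    ngam = ngam)
  list(physiology = phys,
       truth = list(ec_model = ec, flux = flux, net_flux = net, E = E,
                    kcats = true_k, composition = comp, mu = mu,
                    rates = rates, substrate_exchange = sub_ex))
}

#' Simulate MS-level proteomics with a heavy internal standard
#'
#' Emits duplicate-replicate MS records whose light-channel intensities are
#' proportional to the true protein concentrations with multiplicative
#' lognormal noise, tied to a planted heavy internal standard through the
#' heavy/light ratio. The proteome is the model enzymes (at their
#' ground-truth concentrations), a ribosomal block sized to a planted
#' translation rate, and filler proteins absorbing the remaining mass.
#'
#' @param truth the `truth` element of [simulate_condition()].
#' @param condition condition label for the records.
#' @param cv lognormal coefficient of variation (0 = noise-free).
#' @param n_replicates number of replicates (default 2).
#' @param n_other number of non-model filler proteins.
#' @param n_rib number of ribosomal proteins.
#' @param translation_aa_per_s planted translation rate, aa/s.
#' @param undetected enzyme ids withheld from the output (emulating
#'   proteins below detection; default: xylulokinase, never detected).
#' @param saturation planted average enzyme saturation: cells hold
#'   `usage / saturation` of each enzyme (default 0.35).
#' @param headroom extra abundance factor beyond the saturation-consistent
#'   level (default 1.3), giving the enzyme budget slack over the exact
#'   flux requirement.
#' @param seed integer seed.
#' @return list with `records` (MS record data.frame), `true_conc`
#'   (ug/g_protein), `ribosomal_ids`, `f_true` (model-enzyme mass fraction),
#'   `n_rib_mol_per_gdcw`.
#' @export
simulate_proteomics <- function(truth, condition = "exp", cv = 0.05,
                                n_replicates = 2, n_other = 60, n_rib = 20,
                                translation_aa_per_s = 3.0,
                                undetected = "E_XK", saturation = 0.35,
                                headroom = 1.3, seed = 1) {
  set.seed(seed + 1000)
  Ptot <- truth$composition$protein
  mu <- truth$mu
  mw_enz <- setNames(truth$ec_model$enzymes$mw, truth$ec_model$enzymes$id)
  E <- truth$E[!names(truth$E) %in% undetected]
  E <- E[E > 0]                                      # zero usage = undetected
  E <- E / saturation * headroom                     # abundance held by cells
  conc_enz <- E * mw_enz[names(E)] / Ptot * 1e6      # ug/g_protein
  # ribosomal block: median molar abundance = planted ribosome count
  n_rib_mol <- (mu * Ptot / 110) / (translation_aa_per_s * 3600) # mol/gDCW
  rib_ids <- sprintf("RPL%02d", seq_len(n_rib))
  rib_mw <- round(runif(n_rib, 15, 40), 1)                  # g/mmol
  rib_molar <- rep(n_rib_mol * 1000, n_rib)                 # mmol/gDCW
  conc_rib <- setNames(rib_molar * rib_mw / Ptot * 1e6, rib_ids)
  remaining <- 1e6 - sum(conc_enz) - sum(conc_rib)
  if (remaining <= 0) {
    stop("planted proteome exceeds total protein mass; lower the ",
         "translation rate or enzyme abundances", call. = FALSE)
  }
  other_ids <- sprintf("OTH%03d", seq_len(n_other))
  w <- rlnorm(n_other, 0, 1)
  conc_other <- setNames(remaining * w / sum(w), other_ids)
  other_mw <- round(runif(n_other, 20, 120), 1)
  conc <- c(conc_enz, conc_rib, conc_other)
  mw_all <- c(mw_enz[names(conc_enz)],
              setNames(rib_mw, rib_ids), setNames(other_mw, other_ids))
  std <- rlnorm(length(conc), log(1e7), 0.3)  # heavy standard intensities
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  recs <- list()
  for (rep_i in seq_len(n_replicates)) {
    noise <- if (cv > 0) rlnorm(length(conc), -0.5 * sdlog^2, sdlog) else
      rep(1, length(conc))
    light <- conc * noise
    recs[[rep_i]] <- data.frame(
      protein_id = names(conc), condition = condition, replicate = rep_i,
      ibaq_heavy = std, ratio_hl = std / light,
      mw_g_per_mol = unname(mw_all[names(conc)]) * 1000,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(records = do.call(rbind, recs),
       true_conc = conc,
       ribosomal_ids = rib_ids,
       f_true = sum(conc_enz) / 1e6,
       n_rib_mol_per_gdcw = n_rib_mol)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits `model.json`, `kcats.tsv`, `physiology.yaml`, `proteomics.tsv` and
#' `truth.json` for one condition, ready for [run_condition()].
#'
#' @param out_dir output directory (created if needed).
#' @param variant toy network variant.
#' @param phase growth phase.
#' @param seed integer seed.
#' @param cv proteomics noise CV; `rate_cv` physiology noise CV.
#' @param rate_cv physiology noise CV.
#' @return invisibly, the list of written paths.
#' @export
simulate_bundle <- function(out_dir, variant = "glucose", phase = "exp",
                            seed = 1, cv = 0.05, rate_cv = 0.01) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- make_toy_network(variant)
  sim <- simulate_condition(model, phase = phase, rate_cv = rate_cv,
                            seed = seed)
  prot <- simulate_proteomics(sim$truth, condition = paste0(variant, "_",
                                                            phase),
                              cv = cv, seed = seed)
  paths <- list(
    model = file.path(out_dir, "model.json"),
    kcats = file.path(out_dir, "kcats.tsv"),
    physiology = file.path(out_dir, "physiology.yaml"),
    proteomics = file.path(out_dir, "proteomics.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_model(model, paths$model, "json")
  write_tsv(make_toy_kcat_db(model, seed = seed), paths$kcats)
  phys <- sim$physiology
  yaml::write_yaml(list(mu = phys$mu, uptake = as.list(phys$uptake),
                        co2 = phys$co2, o2 = phys$o2,
                        byproducts = as.list(phys$byproducts),
                        Ptot = phys$Ptot, Ptot_sd = phys$Ptot_sd,
                        lipid = phys$lipid,
                        acyl_profile = as.list(phys$acyl_profile),
                        ngam = phys$ngam),
                   paths$physiology)
  write_tsv(prot$records, paths$proteomics)
  jsonlite::write_json(
    list(mu = sim$truth$mu, E = as.list(sim$truth$E),
         net_flux = as.list(sim$truth$net_flux),
         true_conc = as.list(prot$true_conc),
         f_true = prot$f_true,
         ribosomal_ids = prot$ribosomal_ids,
         rates = sim$truth$rates),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Random small stoichiometric model for solver cross-checks
#'
#' Draws a random sparse stoichiometric matrix with random bounds and a
#' random objective; used to compare the simplex against the
#' vertex-enumeration reference on many small instances.
#'
#' @param seed integer seed.
#' @param n_mets,n_rxns dimensions (kept small; enumeration is exponential).
#' @return a `metabolic_model` (gene-rule free).
#' @export
make_random_toy_model <- function(seed, n_mets = 4, n_rxns = 10) {
  set.seed(seed)
  mids <- sprintf("m%02d", seq_len(n_mets))
  mets <- data.frame(id = mids, name = mids, compartment = "c",
                     formula = NA_character_, charge = NA_real_,
                     stringsAsFactors = FALSE)
  rxns <- list()
  for (j in seq_len(n_rxns)) {
    k <- sample(1:min(3, n_mets), 1)
    picks <- sample(mids, k)
    coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    lb <- round(runif(1, -8, 0), 3)
    ub <- round(runif(1, 0, 8), 3)
    rxns[[j]] <- new_reaction(sprintf("r%02d", j), setNames(coef, picks),
                              lb = lb, ub = ub)
  }
  new_model(paste0("rand", seed), c(c = "cytosol"), mets, rxns,
            objective = rxns[[length(rxns)]]$id)
}
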