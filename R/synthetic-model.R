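# Deterministic generator for the synthetic compartmentalized plant model.
#
# The toy network spans cytosol (c), mitochondrion (m), plastid (p),
# peroxisome (x) and vacuole (v) and contains: PSII/PSI photon inputs with
# linear (-> NADPH) and cyclic (-> proton gradient only) electron flow,
# thylakoid-lumen protons (h_lum_p) and a plastid ATP synthase; a lumped
# Calvin cycle; cytosolic glycolysis and sucrose metabolism (invertase,
# sucrose synthase, vacuolar invertase); a full TCA cycle; a proton-explicit
# respiratory chain (10 H+ translocated per NADH, 6 per succinate, ATP
# synthase consuming 16/3 H+ per ATP, giving P/O ratios of exactly 1.875 and
# 1.125); plastidic GS and NADH-GOGAT with the NR/NiR nitrate route; a
# compact photorespiration loop through the peroxisome; and lumped synthesis
# routes for all 47 biomass components (20 amino acids, 5 nucleotide pools,
# starch/sucrose/cellulose, 4 lipid classes, chlorophyll a/b, 7 cofactor
# pools, 6 mineral ions).  The boundary is attached through the standard
# reconstruction machinery: exactly 22 `_Cyto_tx` exchanges and 47
# `_biomass` drains.
#
# Every biochemical reaction is elementally balanced.  Core energy reactions
# (photosystems, electron transport, ATP synthases, central carbon) are
# written with exact stoichiometry and asserted to balance; lumped synthesis
# reactions state their carbon/nitrogen/sulfur backbone and energy cost
# explicitly and are completed with CO2/H2O/H+/Pi/NH4/H2S bookkeeping
# species by a triangular element-balancing step.

# Elemental formulas of the bare species (compartment-independent).  Redox
# pairs differ by the hydrogen-equivalents they carry (NADH = NAD + H2,
# reduced ferredoxin/plastocyanin/cytochrome = oxidized + H), so electron
# bookkeeping reduces to hydrogen bookkeeping.  Ferredoxin and plastocyanin
# use compact synthetic protein-fragment formulas.
.TOY_FORMULAS <- c(
  photon2 = "", photon1 = "",
  h2o = "H2O", h = "H", h_lum = "H", h_im = "H", o2 = "O2", co2 = "CO2",
  pi = "H3O4P", nh4 = "H4N", no3 = "HNO3", no2 = "HNO2", so4 = "H2O4S",
  h2s = "H2S", h2o2 = "H2O2",
  glc = "C6H12O6", fru = "C6H12O6", suc = "C12H22O11",
  starch = "C6H10O5", cellulose = "C6H10O5",
  g6p = "C6H13O9P", f6p = "C6H13O9P", g1p = "C6H13O9P",
  g3p = "C3H7O6P", `3pg` = "C3H7O7P", pep = "C3H5O6P", pyr = "C3H4O3",
  rubp = "C5H12O11P2", r5p = "C5H11O8P",
  pglyc = "C2H5O6P", glyc = "C2H4O3", glx = "C2H2O3",
  cit = "C6H8O7", icit = "C6H8O7", akg = "C5H6O5", succ = "C4H6O4",
  fum = "C4H4O4", mal = "C4H6O5", oaa = "C4H4O5",
  coa = "C21H36N7O16P3S", accoa = "C23H38N7O17P3S",
  succoa = "C25H40N7O19P3S",
  nad = "C21H27N7O14P2", nadh = "C21H29N7O14P2",
  nadp = "C21H28N7O17P3", nadph = "C21H30N7O17P3",
  q = "C49H74O4", qh2 = "C49H76O4", pq = "C53H80O2", pqh2 = "C53H82O2",
  cytcox = "C42H54FeN8O6S2", cytcred = "C42H55FeN8O6S2",
  fdox = "C6H10Fe2N2O4S4", fdred = "C6H11Fe2N2O4S4",
  pcox = "C9H14CuN4O3S", pcred = "C9H15CuN4O3S",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", gtp = "C10H16N5O14P3",
  ctp = "C9H16N3O14P3", utp = "C9H15N2O15P3", dntp = "C10H16N5O12P3",
  ala = "C3H7NO2", arg = "C6H14N4O2", asn = "C4H8N2O3", asp = "C4H7NO4",
  cys = "C3H7NO2S", gln = "C5H10N2O3", glu = "C5H9NO4", gly = "C2H5NO2",
  his = "C6H9N3O2", ile = "C6H13NO2", leu = "C6H13NO2", lys = "C6H14N2O2",
  met = "C5H11NO2S", phe = "C9H11NO2", pro = "C5H9NO2", ser = "C3H7NO3",
  thr = "C4H9NO3", trp = "C11H12N2O2", tyr = "C9H11NO3", val = "C5H11NO2",
  lipid_pc = "C40H80NO8P", lipid_pe = "C37H74NO8P",
  lipid_gal = "C45H86O10", lipid_tag = "C55H98O6",
  chla = "C55H72MgN4O5", chlb = "C55H70MgN4O6",
  k = "K", ca = "Ca", mg = "Mg", fe = "Fe", cl = "Cl", mn = "Mn",
  zn = "Zn", cu = "Cu", mo = "Mo"
)

.toy_bare <- function(met_id) sub("_([cmpxv])$", "", met_id)

.toy_counts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(.TOY_FORMULAS, parse_formula)
    }
    cache
  }
})

# Element residual (produced minus consumed atoms) of a stoichiometry over
# the bare-species formula table.
.toy_residual <- function(st) {
  counts <- .toy_counts()
  resid <- numeric(0)
  for (k in seq_along(st)) {
    bare <- .toy_bare(names(st)[k])
    f <- counts[[bare]]
    if (is.null(f)) next # massless species (photons)
    for (el in names(f)) {
      resid[el] <- (if (el %in% names(resid)) resid[el] else 0) +
        st[[k]] * f[[el]]
    }
  }
  resid[abs(resid) > 1e-9]
}

# Complete a reaction with bookkeeping species.  Adders are applied in
# triangular order (each later adder only perturbs elements fixed later):
# N via ammonium, S via sulfide, P via phosphate, C via CO2, O via water,
# H via protons.
.toy_balance <- function(st, comp, exact = FALSE) {
  resid <- .toy_residual(st)
  if (exact) {
    if (length(resid)) {
      stop(sprintf("internal: reaction declared exact is imbalanced (%s)",
                   paste(sprintf("%s=%g", names(resid), resid),
                         collapse = ", ")))
    }
    return(st)
  }
  adders <- list(c("N", "nh4"), c("S", "h2s"), c("P", "pi"),
                 c("C", "co2"), c("O", "h2o"), c("H", "h"))
  allowed <- list(nh4 = c("c", "m", "p"), h2s = "c", pi = c("c", "m", "p"),
                  co2 = c("c", "m", "p"), h2o = c("c", "m", "p", "x", "v"),
                  h = c("c", "m", "p"))
  for (ad in adders) {
    el <- ad[1]; sp <- ad[2]
    resid <- .toy_residual(st)
    if (!el %in% names(resid)) next
    if (!comp %in% allowed[[sp]]) {
      stop(sprintf("internal: cannot balance %s in compartment '%s'", el, comp))
    }
    id <- paste0(sp, "_", comp)
    st[id] <- (if (id %in% names(st)) st[[id]] else 0) - resid[[el]]
    st <- st[st != 0]
  }
  resid <- .toy_residual(st)
  if (length(resid)) {
    stop(sprintf("internal: residual after balancing (%s)",
                 paste(names(resid), collapse = ", ")))
  }
  st
}

# Reaction recipes: list(id, st, sub, comp, lb, ub, exact, gpr).
.toy_recipes <- function() {
  r <- function(id, st, sub, comp, lb = 0, ub = 1000, exact = FALSE,
                gpr = TRUE) {
    list(id = id, st = st, sub = sub, comp = comp, lb = lb, ub = ub,
         exact = exact, gpr = gpr)
  }
  rev <- -1000
  list(
    # --- photosynthetic electron transport (plastid) ---------------------
    r("PSII_p", c(h2o_p = -2, photon2_p = -4, pq_p = -2, h_p = -4,
                  o2_p = 1, pqh2_p = 2, h_lum_p = 4), "lef", "p",
      exact = TRUE),
    r("B6F_p", c(pqh2_p = -1, pcox_p = -2, h_p = -4, pq_p = 1, pcred_p = 2,
                 h_lum_p = 4), "lef", "p", exact = TRUE),
    r("PSI_p", c(pcred_p = -1, photon1_p = -1, fdox_p = -1, pcox_p = 1,
                 fdred_p = 1), "lef", "p", exact = TRUE),
    r("FNR_p", c(fdred_p = -2, nadp_p = -1, fdox_p = 2, nadph_p = 1),
      "lef", "p"),
    r("CEF_p", c(fdred_p = -2, pq_p = -1, fdox_p = 2, pqh2_p = 1),
      "cef", "p"),
    r("ATPS_p", c(adp_p = -1, pi_p = -1, h_lum_p = -14 / 3, atp_p = 1,
                  h2o_p = 1, h_p = 14 / 3), "atp_synthase_plastid", "p",
      exact = TRUE),
    # --- Calvin cycle (lumped) and plastid starch ------------------------
    r("RBC_p", c(rubp_p = -1, co2_p = -1, h2o_p = -1, `3pg_p` = 2),
      "calvin", "p", exact = TRUE),
    r("PGK_GAPDH_p", c(`3pg_p` = -1, atp_p = -1, nadph_p = -1, g3p_p = 1,
                       adp_p = 1, pi_p = 1, nadp_p = 1), "calvin", "p",
      lb = rev, exact = TRUE),
    r("CALVIN_REGEN_p", c(g3p_p = -5, atp_p = -3, h2o_p = -2, rubp_p = 3,
                          adp_p = 3, pi_p = 2), "calvin", "p", exact = TRUE),
    r("FBP_p", c(g3p_p = -2, h2o_p = -1, f6p_p = 1, pi_p = 1), "calvin",
      "p", exact = TRUE),
    r("PGI_p", c(f6p_p = -1, g6p_p = 1), "calvin", "p", lb = rev,
      exact = TRUE),
    r("STARCH_SYN_p", c(g6p_p = -1, atp_p = -1, h2o_p = -1, starch_p = 1,
                        adp_p = 1, pi_p = 2), "starch", "p", exact = TRUE),
    # --- photorespiration ------------------------------------------------
    r("RBO_p", c(rubp_p = -1, o2_p = -1, `3pg_p` = 1, pglyc_p = 1),
      "photorespiration", "p", exact = TRUE),
    r("PGP_p", c(pglyc_p = -1, h2o_p = -1, glyc_p = 1, pi_p = 1),
      "photorespiration", "p", exact = TRUE),
    r("GOX_x", c(glyc_x = -1, o2_x = -1, glx_x = 1, h2o2_x = 1),
      "photorespiration", "x", exact = TRUE),
    r("CAT_x", c(h2o2_x = -2, h2o_x = 2, o2_x = 1), "photorespiration",
      "x", exact = TRUE),
    r("GGT_c", c(glx_c = -1, glu_c = -1, gly_c = 1, akg_c = 1),
      "photorespiration", "c", exact = TRUE),
    # --- glycolysis / gluconeogenesis (cytosol) --------------------------
    r("HXK_c", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
      "glycolysis", "c", exact = TRUE),
    r("FRK_c", c(fru_c = -1, atp_c = -1, f6p_c = 1, adp_c = 1),
      "glycolysis", "c", exact = TRUE),
    r("PGI_c", c(g6p_c = -1, f6p_c = 1), "glycolysis", "c", lb = rev,
      exact = TRUE),
    r("PGM_c", c(g1p_c = -1, g6p_c = 1), "glycolysis", "c", lb = rev,
      exact = TRUE),
    r("PFK_ALD_c", c(f6p_c = -1, atp_c = -1, g3p_c = 2, adp_c = 1),
      "glycolysis", "c", exact = TRUE),
    r("FBP_c", c(g3p_c = -2, h2o_c = -1, f6p_c = 1, pi_c = 1),
      "glycolysis", "c", exact = TRUE),
    r("GAPDH_PGK_c", c(g3p_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
                       `3pg_c` = 1, nadh_c = 1, atp_c = 1), "glycolysis",
      "c", lb = rev, exact = TRUE),
    r("ENO_c", c(`3pg_c` = -1, pep_c = 1, h2o_c = 1), "glycolysis", "c",
      lb = rev, exact = TRUE),
    r("PYK_c", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
      "glycolysis", "c", exact = TRUE),
    r("PEPC_c", c(pep_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1, pi_c = 1),
      "anaplerosis", "c", exact = TRUE),
    r("MDH_c", c(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1),
      "shuttle", "c", lb = rev, exact = TRUE),
    # --- sucrose metabolism ----------------------------------------------
    # cytosolic sucrose utilization carries one ATP per sucrose, lumping the
    # plasma-membrane H+-ATPase cost of proton-coupled sucrose import with
    # cleavage (active transmembrane transport is not free)
    r("INV_c", c(suc_c = -1, h2o_c = -1, atp_c = -1, glc_c = 1, fru_c = 1,
                 adp_c = 1, pi_c = 1), "sucrose", "c"),
    r("SUS_c", c(suc_c = -1, atp_c = -1, fru_c = 1, g1p_c = 1, adp_c = 1),
      "sucrose", "c"),
    r("SPS_c", c(f6p_c = -1, g1p_c = -1, atp_c = -1, h2o_c = -2, suc_c = 1,
                 adp_c = 1, pi_c = 3), "sucrose", "c", exact = TRUE),
    r("INV_v", c(suc_v = -1, h2o_v = -1, glc_v = 1, fru_v = 1),
      "sucrose", "v", exact = TRUE),
    r("AMY_c", c(starch_c = -1, h2o_c = -1, glc_c = 1), "starch", "c",
      exact = TRUE),
    r("CESA_c", c(g6p_c = -1, atp_c = -1, h2o_c = -1, cellulose_c = 1,
                  adp_c = 1, pi_c = 2), "cellulose", "c", exact = TRUE),
    # --- pyruvate oxidation and TCA cycle (mitochondrion) ----------------
    r("PDH_m", c(pyr_m = -1, coa_m = -1, nad_m = -1, accoa_m = 1,
                 co2_m = 1, nadh_m = 1), "pdh", "m", exact = TRUE),
    r("CS_m", c(accoa_m = -1, oaa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1),
      "tca", "m", exact = TRUE),
    r("ACO_m", c(cit_m = -1, icit_m = 1), "tca", "m", lb = rev,
      exact = TRUE),
    r("IDH_m", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
      "tca", "m", exact = TRUE),
    r("OGDH_m", c(akg_m = -1, coa_m = -1, nad_m = -1, succoa_m = 1,
                  co2_m = 1, nadh_m = 1), "tca", "m", exact = TRUE),
    r("SCS_m", c(succoa_m = -1, adp_m = -1, pi_m = -1, succ_m = 1,
                 atp_m = 1, coa_m = 1), "tca", "m", exact = TRUE),
    r("SDH_m", c(succ_m = -1, q_m = -1, fum_m = 1, qh2_m = 1), "tca", "m",
      exact = TRUE),
    r("FUM_m", c(fum_m = -1, h2o_m = -1, mal_m = 1), "tca", "m", lb = rev,
      exact = TRUE),
    r("MDH_m", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1), "tca",
      "m", lb = rev, exact = TRUE),
    # --- respiratory chain, protons explicit to the membrane space -------
    r("CPLX1_m", c(nadh_m = -1, q_m = -1, h_m = -4, nad_m = 1, qh2_m = 1,
                   h_im_m = 4), "oxphos", "m", exact = TRUE),
    r("CPLX3_m", c(qh2_m = -1, cytcox_m = -2, h_m = -4, q_m = 1,
                   cytcred_m = 2, h_im_m = 4), "oxphos", "m", exact = TRUE),
    r("CPLX4_m", c(cytcred_m = -2, o2_m = -0.5, h_m = -2, cytcox_m = 2,
                   h2o_m = 1, h_im_m = 2), "oxphos", "m", exact = TRUE),
    r("ATPS_m", c(adp_m = -1, pi_m = -1, h_im_m = -16 / 3, atp_m = 1,
                  h2o_m = 1, h_m = 16 / 3), "atp_synthase_mito", "m",
      exact = TRUE),
    # --- nitrogen assimilation -------------------------------------------
    r("NR_c", c(no3_c = -1, nadh_c = -1, no2_c = 1, nad_c = 1, h2o_c = 1),
      "nitrate_reduction", "c", exact = TRUE),
    r("NiR_p", c(no2_p = -1, fdred_p = -6, h_p = -1, nh4_p = 1, fdox_p = 6,
                 h2o_p = 2), "nitrate_reduction", "p", exact = TRUE),
    r("GS_p", c(glu_p = -1, nh4_p = -1, atp_p = -1, gln_p = 1, adp_p = 1,
                pi_p = 1, h_p = 1), "gs", "p", exact = TRUE),
    r("GOGAT_p", c(gln_p = -1, akg_p = -1, nadh_p = -1, glu_p = 2,
                   nad_p = 1), "gogat", "p", exact = TRUE),
    r("MDH_p", c(oaa_p = -1, nadh_p = -1, mal_p = 1, nad_p = 1), "shuttle",
      "p", lb = rev, exact = TRUE),
    r("GDH_m", c(glu_m = -1, nad_m = -1, h2o_m = -1, h_m = -1, akg_m = 1,
                 nh4_m = 1, nadh_m = 1), "nitrogen", "m", exact = TRUE),
    # --- sulfate assimilation --------------------------------------------
    r("SAT_c", c(so4_c = -1, nadph_c = -4, atp_c = -1, h2s_c = 1,
                 nadp_c = 4, adp_c = 1, pi_c = 1, h2o_c = 3), "sulfur",
      "c", exact = TRUE),
    # --- amino-acid synthesis (lumped, cytosol) --------------------------
    r("ALA_SYN_c", c(pyr_c = -1, glu_c = -1, ala_c = 1, akg_c = 1),
      "amino_acid", "c", exact = TRUE),
    r("ASP_SYN_c", c(oaa_c = -1, glu_c = -1, asp_c = 1, akg_c = 1),
      "amino_acid", "c", exact = TRUE),
    r("ASN_SYN_c", c(asp_c = -1, gln_c = -1, atp_c = -1, asn_c = 1,
                     glu_c = 1, adp_c = 1, pi_c = 1), "amino_acid", "c"),
    r("SER_SYN_c", c(`3pg_c` = -1, glu_c = -1, nad_c = -1, ser_c = 1,
                     akg_c = 1, nadh_c = 1, pi_c = 1), "amino_acid", "c"),
    r("GLY_SYN_c", c(ser_c = -1, nad_c = -1, gly_c = 1, nadh_c = 1),
      "amino_acid", "c"),
    r("CYS_SYN_c", c(ser_c = -1, h2s_c = -1, atp_c = -1, cys_c = 1,
                     adp_c = 1, pi_c = 1), "amino_acid", "c"),
    r("VAL_SYN_c", c(pyr_c = -2, glu_c = -1, nadph_c = -1, val_c = 1,
                     akg_c = 1, nadp_c = 1), "amino_acid", "c"),
    r("LEU_SYN_c", c(pyr_c = -3, glu_c = -1, nadph_c = -1, leu_c = 1,
                     akg_c = 1, nadp_c = 1), "amino_acid", "c"),
    r("ILE_SYN_c", c(pyr_c = -2, glu_c = -1, atp_c = -1, nadph_c = -2,
                     ile_c = 1, akg_c = 1, adp_c = 1, pi_c = 1,
                     nadp_c = 2), "amino_acid", "c"),
    r("LYS_SYN_c", c(oaa_c = -1, pyr_c = -1, glu_c = -2, atp_c = -1,
                     nadph_c = -2, lys_c = 1, akg_c = 2, adp_c = 1,
                     pi_c = 1, nadp_c = 2), "amino_acid", "c"),
    r("THR_SYN_c", c(asp_c = -1, atp_c = -2, nadph_c = -2, thr_c = 1,
                     adp_c = 2, pi_c = 2, nadp_c = 2), "amino_acid", "c"),
    r("MET_SYN_c", c(asp_c = -1, ser_c = -1, h2s_c = -1, atp_c = -2,
                     nadph_c = -2, met_c = 1, gly_c = 1, adp_c = 2,
                     pi_c = 2, nadp_c = 2), "amino_acid", "c"),
    r("PRO_SYN_c", c(glu_c = -1, atp_c = -1, nadph_c = -2, pro_c = 1,
                     adp_c = 1, pi_c = 1, nadp_c = 2), "amino_acid", "c"),
    r("ARG_SYN_c", c(glu_c = -1, gln_c = -1, asp_c = -1, atp_c = -3,
                     arg_c = 1, akg_c = 1, fum_c = 1, adp_c = 3, pi_c = 3),
      "amino_acid", "c"),
    r("PHE_SYN_c", c(pep_c = -2, f6p_c = -1, glu_c = -1, atp_c = -1,
                     nadph_c = -1, phe_c = 1, akg_c = 1, adp_c = 1,
                     nadp_c = 1), "amino_acid", "c"),
    r("TYR_SYN_c", c(pep_c = -2, f6p_c = -1, glu_c = -1, atp_c = -1,
                     nad_c = -1, tyr_c = 1, akg_c = 1, adp_c = 1,
                     nadh_c = 1), "amino_acid", "c"),
    r("TRP_SYN_c", c(pep_c = -2, f6p_c = -1, r5p_c = -1, gln_c = -1,
                     ser_c = -1, atp_c = -2, trp_c = 1, glu_c = 1,
                     pyr_c = 1, adp_c = 2), "amino_acid", "c"),
    r("HIS_SYN_c", c(r5p_c = -1, gln_c = -3, atp_c = -1, nad_c = -2,
                     his_c = 1, glu_c = 3, adp_c = 1, nadh_c = 2),
      "amino_acid", "c"),
    # --- pentose phosphate (oxidative, lumped) ---------------------------
    r("G6PDH_c", c(g6p_c = -1, nadp_c = -2, h2o_c = -1, r5p_c = 1,
                   co2_c = 1, nadph_c = 2), "ppp", "c", exact = TRUE),
    r("TKT_TAL_c", c(r5p_c = -3, f6p_c = 2, g3p_c = 1), "ppp", "c",
      lb = rev, exact = TRUE),
    # --- nucleotide synthesis (lumped, cytosol) --------------------------
    r("ADE_SYN_c", c(r5p_c = -1, gln_c = -2, asp_c = -2, gly_c = -1,
                     atp_c = -5, glu_c = 2, fum_c = 2, adp_c = 6),
      "nucleotide", "c"),
    r("GUA_SYN_c", c(r5p_c = -1, gln_c = -3, asp_c = -1, gly_c = -1,
                     atp_c = -6, nad_c = -1, gtp_c = 1, glu_c = 3,
                     fum_c = 1, adp_c = 6, nadh_c = 1), "nucleotide", "c"),
    r("URA_SYN_c", c(r5p_c = -1, gln_c = -1, asp_c = -1, atp_c = -3,
                     nad_c = -1, utp_c = 1, glu_c = 1, adp_c = 3,
                     nadh_c = 1), "nucleotide", "c"),
    r("CTP_SYN_c", c(utp_c = -1, gln_c = -1, atp_c = -1, ctp_c = 1,
                     glu_c = 1, adp_c = 1), "nucleotide", "c"),
    r("DNTP_SYN_c", c(atp_c = -1, nadph_c = -1, dntp_c = 1, nadp_c = 1,
                      h2o_c = 1), "nucleotide", "c", exact = TRUE),
    # --- lipid synthesis (lumped, cytosol) -------------------------------
    r("LIPID_PC_SYN_c", c(g3p_c = -1, pyr_c = -17, ser_c = -1,
                          nadph_c = -14, atp_c = -6, lipid_pc_c = 1,
                          nadp_c = 14, adp_c = 6), "lipid", "c"),
    r("LIPID_PE_SYN_c", c(g3p_c = -1, pyr_c = -16, ser_c = -1,
                          nadph_c = -13, atp_c = -6, lipid_pe_c = 1,
                          nadp_c = 13, adp_c = 6), "lipid", "c"),
    r("LIPID_GAL_SYN_c", c(g3p_c = -1, g6p_c = -1, pyr_c = -16,
                           nadph_c = -14, atp_c = -5, lipid_gal_c = 1,
                           nadp_c = 14, adp_c = 5), "lipid", "c"),
    r("LIPID_TAG_SYN_c", c(g3p_c = -1, pyr_c = -26, nadph_c = -23,
                           atp_c = -9, lipid_tag_c = 1, nadp_c = 23,
                           adp_c = 9), "lipid", "c"),
    # --- chlorophylls (plastid) ------------------------------------------
    r("CHLA_SYN_p", c(glu_p = -4, g3p_p = -12, mg_p = -1, atp_p = -3,
                      nadph_p = -6, chla_p = 1, adp_p = 3, nadp_p = 6),
      "pigment", "p"),
    r("CHLB_SYN_p", c(glu_p = -4, g3p_p = -12, mg_p = -1, atp_p = -3,
                      nadph_p = -5, nad_p = -1, chlb_p = 1, adp_p = 3,
                      nadp_p = 5, nadh_p = 1), "pigment", "p"),
    # --- cofactor pools (lumped, cytosol) --------------------------------
    r("NAD_SYN_c", c(r5p_c = -2, gln_c = -4, asp_c = -2, gly_c = -1,
                     atp_c = -7, nad_c = 1, glu_c = 4, fum_c = 2,
                     adp_c = 7), "cofactor", "c"),
    r("NADP_SYN_c", c(nad_c = -1, atp_c = -1, nadp_c = 1, adp_c = 1),
      "cofactor", "c", exact = TRUE),
    r("COA_SYN_c", c(r5p_c = -1, gln_c = -3, asp_c = -2, gly_c = -1,
                     cys_c = -1, pyr_c = -1, atp_c = -6, coa_c = 1,
                     glu_c = 3, fum_c = 2, adp_c = 6), "cofactor", "c"),
    r("Q_SYN_c", c(pep_c = -2, f6p_c = -1, pyr_c = -22, atp_c = -3,
                   nadph_c = -2, q_c = 1, adp_c = 3, nadp_c = 2),
      "cofactor", "c"),
    r("PQ_SYN_c", c(pep_c = -2, f6p_c = -1, pyr_c = -24, atp_c = -3,
                    nadph_c = -2, pq_c = 1, adp_c = 3, nadp_c = 2),
      "cofactor", "c"),
    r("FD_SYN_c", c(cys_c = -2, fe_c = -2, h2s_c = -2, atp_c = -2,
                    fdox_c = 1, adp_c = 2), "cofactor", "c"),
    r("PC_SYN_c", c(his_c = -1, cys_c = -1, cu_c = -1, atp_c = -1,
                    pcox_c = 1, adp_c = 1), "cofactor", "c"),
    # --- intracellular transport (all through the cytosol hub) -----------
    .toy_transport("Photon2", "photon2", "p", into = TRUE, gpr = FALSE),
    .toy_transport("Photon1", "photon1", "p", into = TRUE, gpr = FALSE),
    .toy_transport("CO2", "co2", "p", gpr = FALSE),
    .toy_transport("CO2", "co2", "m", gpr = FALSE),
    .toy_transport("O2", "o2", "p", gpr = FALSE),
    .toy_transport("O2", "o2", "m", gpr = FALSE),
    .toy_transport("O2", "o2", "x", gpr = FALSE),
    .toy_transport("H2O", "h2o", "p", gpr = FALSE),
    .toy_transport("H2O", "h2o", "m", gpr = FALSE),
    .toy_transport("H2O", "h2o", "x", gpr = FALSE),
    .toy_transport("H2O", "h2o", "v", gpr = FALSE),
    .toy_transport("H", "h", "p", gpr = FALSE),
    .toy_transport("H", "h", "m", gpr = FALSE),
    .toy_transport("Pi", "pi", "p"),
    .toy_transport("Pi", "pi", "m"),
    r("ATP_ADP_pc", c(atp_c = -1, adp_p = -1, atp_p = 1, adp_c = 1),
      "transport", "p", lb = rev, exact = TRUE),
    r("ATP_ADP_mc", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
      "transport", "m", exact = TRUE),
    .toy_transport("3PG", "3pg", "p"),
    .toy_transport("G3P", "g3p", "p"),
    .toy_transport("G6P", "g6p", "p"),
    .toy_transport("Starch", "starch", "p", out = TRUE),
    .toy_transport("Mal", "mal", "m"),
    .toy_transport("OAA", "oaa", "m"),
    .toy_transport("Mal", "mal", "p"),
    .toy_transport("OAA", "oaa", "p"),
    .toy_transport("Pyr", "pyr", "m", into = TRUE),
    .toy_transport("AKG", "akg", "p"),
    .toy_transport("AKG", "akg", "m"),
    .toy_transport("Glu", "glu", "p"),
    .toy_transport("Glu", "glu", "m"),
    .toy_transport("Gln", "gln", "p"),
    .toy_transport("NH4", "nh4", "p", into = TRUE),
    .toy_transport("NH4", "nh4", "m"),
    .toy_transport("NO2", "no2", "p", into = TRUE),
    .toy_transport("Fum", "fum", "m"),
    .toy_transport("Succ", "succ", "m"),
    r("Suc_vc", c(suc_c = -1, atp_c = -1, h2o_c = -1, suc_v = 1, adp_c = 1,
                  pi_c = 1), "sucrose", "c", exact = TRUE),
    .toy_transport("Glc", "glc", "v", out = TRUE, sub = "sucrose"),
    .toy_transport("Fru", "fru", "v", out = TRUE, sub = "sucrose"),
    .toy_transport("Chla", "chla", "p", out = TRUE, sub = "pigment"),
    .toy_transport("Chlb", "chlb", "p", out = TRUE, sub = "pigment"),
    .toy_transport("Mg", "mg", "p", into = TRUE),
    .toy_transport("Glyc", "glyc", "p", out = TRUE,
                   sub = "photorespiration"),
    .toy_transport("Glyc", "glyc", "x", sub = "photorespiration"),
    .toy_transport("Glx", "glx", "x", out = TRUE, sub = "photorespiration")
  )
}

# Transport recipe helper.  Direction: reversible by default; `into = TRUE`
# runs cytosol -> compartment only, `out = TRUE` compartment -> cytosol only.
.toy_transport <- function(label, sp, comp, into = FALSE, out = FALSE,
                           sub = "transport", gpr = TRUE) {
  from <- paste0(sp, "_", comp)
  to <- paste0(sp, "_c")
  st <- stats::setNames(c(-1, 1), c(from, to))
  lb <- if (into || out) 0 else -1000
  if (into) st <- -st # cytosol -> compartment
  list(id = paste0(label, "_", comp, "c"), st = st, sub = sub, comp = comp,
       lb = lb, ub = 1000, exact = TRUE, gpr = gpr)
}

# Default soil-grown free amino-acid pool (umol per gDW).  Total is exactly
# 100; the top five (Gln, Ser, Asn, Pro, Val) dominate, with glutamine
# largest, mirroring leaf free-pool measurements.
.toy_aa_soil <- c(
  Gln = 25, Ser = 15, Asn = 12, Pro = 12, Val = 10,
  Ala = 3, Arg = 1.5, Asp = 4, Cys = 0.5, Glu = 5.2, Gly = 2, His = 0.8,
  Ile = 1.2, Leu = 1.5, Lys = 1.3, Met = 0.5, Phe = 1.2, Thr = 1.8,
  Trp = 0.4, Tyr = 1.1
)

# The 22-exchange / 47-drain boundary specification.
.toy_boundary_spec <- function() {
  ex <- function(label, species, direction = "import", bound = 1000) {
    data.frame(label = label, species = species, direction = direction,
               bound = bound, stringsAsFactors = FALSE)
  }
  exchanges <- rbind(
    ex("Glc", "glc_c"), ex("Sucrose", "suc_c"), ex("Starch", "starch_c"),
    ex("PhotonPSII", "photon2_c"), ex("PhotonPSI", "photon1_c"),
    ex("NO3", "no3_c"), ex("NH4", "nh4_c"), ex("SO4", "so4_c"),
    ex("Pi", "pi_c"), ex("Ca", "ca_c"), ex("Fe", "fe_c"), ex("Mg", "mg_c"),
    ex("K", "k_c"), ex("CO2", "co2_c", "both"), ex("O2", "o2_c", "both"),
    ex("H2O", "h2o_c", "both"), ex("H", "h_c", "both"), ex("Cl", "cl_c"),
    ex("Mn", "mn_c"), ex("Zn", "zn_c"), ex("Cu", "cu_c"), ex("Mo", "mo_c"))
  bc <- function(name, component, coefficient) {
    data.frame(name = name, component = component,
               coefficient = coefficient, stringsAsFactors = FALSE)
  }
  aa <- do.call(rbind, lapply(names(.toy_aa_soil), function(a) {
    bc(a, paste0(tolower(a), "_c"), .toy_aa_soil[[a]] / 1000)
  }))
  other <- rbind(
    bc("ATP", "atp_c", 0.010), bc("GTP", "gtp_c", 0.005),
    bc("CTP", "ctp_c", 0.005), bc("UTP", "utp_c", 0.005),
    bc("dNTP", "dntp_c", 0.003),
    bc("Starch", "starch_c", 1.2), bc("Sucrose", "suc_c", 0.25),
    bc("Cellulose", "cellulose_c", 2.8),
    bc("Lipid_PC", "lipid_pc_c", 0.05), bc("Lipid_PE", "lipid_pe_c", 0.04),
    bc("Lipid_Gal", "lipid_gal_c", 0.06),
    bc("Lipid_TAG", "lipid_tag_c", 0.03),
    bc("ChlA", "chla_c", 0.006), bc("ChlB", "chlb_c", 0.002),
    bc("NAD", "nad_c", 0.002), bc("NADP", "nadp_c", 0.001),
    bc("CoA", "coa_c", 0.001), bc("UQ", "q_c", 0.001),
    bc("PQ", "pq_c", 0.001), bc("Fd", "fdox_c", 0.002),
    bc("PCyanin", "pcox_c", 0.002),
    bc("K", "k_c", 0.25), bc("Ca", "ca_c", 0.10), bc("Mg", "mg_c", 0.08),
    bc("Fe", "fe_c", 0.02), bc("Cl", "cl_c", 0.05), bc("Mn", "mn_c", 0.01))
  boundary_spec(exchanges, rbind(aa, other))
}

#' Generator configuration for the synthetic study
#'
#' Collects every tunable of the synthetic data generator: the seed, the
#' RNA-seq abundance model (log-normal base FPKM, multiplicative replicate
#' noise), the condition-specific expression fold changes per pathway tag,
#' the photon/sucrose exchange bounds defining the soil-grown and in-vitro
#' presets, and the free amino-acid fold map (printed folds for Gln, Asn,
#' Ser, Val, Pro; the remaining acids share a common fold solved so the
#' total concentration ratio is exactly `total_aa_ratio`).
#'
#' @param seed Integer seed fixing all generator outputs bit-exactly.
#' @param fpkm_cv Coefficient of variation of replicate FPKM noise.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of base expression.
#' @param expression_folds Named in-vitro/soil mean-expression ratios per
#'   pathway tag (photosynthesis, Calvin, TCA and glycolysis tags below 1;
#'   GS/GOGAT and sucrose tags above 1).
#' @param photon_bounds,sucrose_bounds Named vectors (`soil`, `in_vitro`)
#'   of exchange upper bounds (flux units).
#' @param co2_bounds Named vector (`soil`, `in_vitro`) of CO2 availability
#'   magnitudes; the in-vitro value is small, representing the poor gas
#'   exchange of a sealed culture vessel.
#' @param amino_acid_folds In-vitro/soil concentration folds of the five
#'   reported amino acids.
#' @param total_aa_ratio Target total free amino-acid ratio (in-vitro/soil).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             fpkm_cv = 0.2,
                             fpkm_meanlog = log(20), fpkm_sdlog = 1,
                             expression_folds = c(
                               lef = 0.4, cef = 0.8, calvin = 0.5,
                               photorespiration = 0.6, starch = 0.6,
                               glycolysis = 0.7, sucrose = 2.5, tca = 0.6,
                               pdh = 0.8, oxphos = 0.8,
                               atp_synthase_mito = 0.8,
                               atp_synthase_plastid = 0.7,
                               anaplerosis = 0.9, shuttle = 1.2,
                               nitrate_reduction = 0.6, gs = 3.0,
                               gogat = 2.2, nitrogen = 1.0, sulfur = 1.0,
                               amino_acid = 1.5, nucleotide = 1.0,
                               ppp = 0.8, lipid = 0.6, pigment = 0.5,
                               cofactor = 1.0, cellulose = 0.8,
                               transport = 1.0),
                             photon_bounds = c(soil = 4.5, in_vitro = 1.3),
                             sucrose_bounds = c(soil = 0, in_vitro = 0.06),
                             co2_bounds = c(soil = 1.0, in_vitro = 0.10),
                             amino_acid_folds = c(Gln = 4.92, Asn = 1.92,
                                                  Ser = 1.21, Val = 1.19,
                                                  Pro = 0.82),
                             total_aa_ratio = 2.0) {
  stopifnot(is.numeric(seed), length(seed) == 1L, fpkm_cv >= 0,
            all(expression_folds > 0), all(amino_acid_folds > 0),
            total_aa_ratio > 0,
            all(c("soil", "in_vitro") %in% names(photon_bounds)),
            all(c("soil", "in_vitro") %in% names(sucrose_bounds)),
            all(c("soil", "in_vitro") %in% names(co2_bounds)))
  structure(list(seed = as.integer(seed), fpkm_cv = fpkm_cv,
                 fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
                 expression_folds = expression_folds,
                 photon_bounds = photon_bounds,
                 sucrose_bounds = sucrose_bounds,
                 co2_bounds = co2_bounds,
                 amino_acid_folds = amino_acid_folds,
                 total_aa_ratio = total_aa_ratio),
            class = "generator_config")
}

# Evaluate fn with a private RNG stream seeded from `seed`.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate the synthetic toy plant model
#'
#' Builds the compartmentalized photosynthetic toy network described in the
#' package vignette: 5 compartments, explicit photosystems with linear and
#' cyclic electron flow, proton-explicit respiratory chain (P/O ratios
#' 1.875 for NADH and 1.125 for succinate by construction), GS/GOGAT
#' nitrogen assimilation, lumped biosynthesis of all 47 biomass components,
#' exactly 22 exchange reactions and 47 biomass drains, elementally
#' balanced reactions throughout, and a biomass equation rescaled to
#' exactly 1 g/mmol.  Every enzymatic reaction carries a synthetic GPR
#' (single genes, OR pairs and AND combinations) drawn deterministically
#' from the config seed.
#'
#' @param config A [generator_config()].
#' @return A `metabolic_model` with a `pathways` map and a `gene_pathways`
#'   attribute (gene id -> pathway tag) consumed by
#'   [generate_expression_profiles()].
#' @export
generate_toy_plant_model <- function(config = generator_config()) {
  recipes <- .toy_recipes()
  gprs <- .with_seed(config$seed, function() {
    counter <- 0L
    lapply(recipes, function(rec) {
      if (!rec$gpr) return("")
      gene <- function() {
        counter <<- counter + 1L
        sprintf("g%04d", counter)
      }
      u <- stats::runif(1)
      if (u < 0.60) gene()
      else if (u < 0.85) sprintf("%s or %s", gene(), gene())
      else if (u < 0.95) sprintf("%s and %s", gene(), gene())
      else sprintf("(%s or %s) and %s", gene(), gene(), gene())
    })
  })
  rxns <- vector("list", length(recipes))
  met_ids <- character(0)
  for (k in seq_along(recipes)) {
    rec <- recipes[[k]]
    st <- .toy_balance(rec$st, rec$comp, exact = rec$exact)
    rxns[[k]] <- reaction(rec$id, st, lower_bound = rec$lb,
                          upper_bound = rec$ub, gpr = gprs[[k]],
                          subsystem = rec$sub)
    met_ids <- union(met_ids, names(st))
  }
  spec <- .toy_boundary_spec()
  met_ids <- union(met_ids, spec$exchanges$species)
  met_ids <- union(met_ids, spec$biomass_components$component)
  mets <- lapply(met_ids, function(id) {
    bare <- .toy_bare(id)
    f <- .TOY_FORMULAS[bare]
    if (is.na(f)) stop(sprintf("internal: no formula registered for '%s'", bare))
    metabolite(id, name = bare, formula = if (nzchar(f)) unname(f)
               else NA_character_)
  })
  model <- metabolic_model("toyplant", mets, rxns, objective = rxns[[1]]$id,
                           validate = FALSE)
  model <- add_boundary(model, spec)
  comp <- rescale_biomass(get_biomass_composition(model))
  model <- set_biomass_composition(model, comp)
  model$pathways <- list(
    lef = c("PSII_p", "B6F_p", "PSI_p", "FNR_p"),
    cef = "CEF_p",
    calvin = c("RBC_p", "PGK_GAPDH_p", "CALVIN_REGEN_p", "FBP_p", "PGI_p"),
    glycolysis = c("HXK_c", "FRK_c", "PGI_c", "PFK_ALD_c", "GAPDH_PGK_c",
                   "ENO_c", "PYK_c"),
    tca = c("CS_m", "ACO_m", "IDH_m", "OGDH_m", "SCS_m", "SDH_m", "FUM_m",
            "MDH_m"),
    gs = "GS_p",
    gogat = "GOGAT_p",
    nitrate_reduction = c("NR_c", "NiR_p"),
    sucrose_uptake = c("Sucrose_Cyto_tx", "INV_c", "SUS_c", "Suc_vc",
                       "INV_v"),
    atp_synthase = c("ATPS_p", "ATPS_m"))
  validate_model(model)
  gene_map <- character(0)
  for (k in seq_along(recipes)) {
    genes <- gpr_genes(parse_gpr(gprs[[k]]))
    if (length(genes)) {
      gene_map[genes] <- recipes[[k]]$sub
    }
  }
  attr(model, "gene_pathways") <- gene_map
  model
}
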