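# Generates the reconstructed (synthetic) integrated-model tables under
# inst/extdata/model/. The network is a reconstruction of the integrated
# hypoxia + tumor-signaling model at its published size (189 species,
# 86 reactions, 163 rate parameters): an oxygen-controlled HIF switch
# driving VEGF mRNA, a VEGF/EGF receptor network feeding the
# Ras-RAF-MEK-ERK and PI3K-Akt cascades with ATP-dependent phosphorylation
# steps, plus the constant "inventory" species carried by the published
# species table. Every row is flagged provenance=reconstructed.
#
# Run from the package root:  Rscript data-raw/make_model_tables.R

sp <- function(id, x0, module, phospho = FALSE, pair = "", unit = "nM") {
  data.frame(id = id, initial_conc = x0, unit = unit, module = module,
             is_phospho_form = phospho, phospho_pair = pair,
             provenance = "reconstructed", stringsAsFactors = FALSE)
}
rx <- function(id, reactants, products, law, params, atp = FALSE, target = "") {
  data.frame(id = id, reactants = reactants, products = products,
             rate_law = law, params = params, atp_dependent = atp,
             drug_target = target, provenance = "reconstructed",
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------- HIF module
# Oxygen-dependent prolyl hydroxylation marks HIF for VHL-mediated
# degradation; stabilized HIF translocates, binds ARNT and the HRE, and
# drives mRNA transcription. A PHD negative feedback (HIF-induced PHD
# expression) gives the adaptive transient.

hif_species <- rbind(
  sp("O2",       1,    "hif", unit = "fraction"),
  sp("HIF",      1,    "hif"),
  sp("PHD",      100,  "hif"),
  sp("HIF_OH",   0.1,  "hif"),
  sp("VHL",      100,  "hif"),
  sp("HIF_VHL",  0.1,  "hif"),
  sp("HIFn",     0.5,  "hif"),
  sp("ARNT",     100,  "hif"),
  sp("HIF_ARNT", 0.5,  "hif"),
  sp("HRE",      0.1,  "hif"),
  sp("HIF_HRE",  0.01, "hif"),
  sp("mRNA",     1,    "hif"),
  sp("mRNA_PHD", 1,    "hif"))

# constant inventory of the hypoxia machinery (no reactions; held fixed)
hif_inventory <- c("PHD1", "PHD3", "FIH", "p300", "CBP", "ElonginB",
                   "ElonginC", "Cul2", "Rbx1", "Ub_pool", "Proteasome26S",
                   "Importin", "CRM1", "HSP90", "RACK1", "OS9", "ARD1",
                   "VDU2", "Siah2", "HAF", "Hsp70", "CHIP", "Morg1",
                   "Mint3", "Cited2")
set.seed(42)  # fixed arbitrary inventory concentrations
hif_species <- rbind(hif_species,
                     do.call(rbind, lapply(hif_inventory, function(nm) {
                       sp(nm, signif(10^runif(1, 1, 2.5), 3), "hif")
                     })))

hif_reactions <- rbind(
  rx("h_hif_syn",   "",                "HIF",              "mass_action", "kf=0.4"),
  rx("h_hif_ohase", "HIF + PHD + O2",  "HIF_OH + PHD + O2","mass_action", "kf=0.5"),
  rx("h_vhl_bind",  "HIF_OH + VHL",    "HIF_VHL",          "mass_action", "kf=0.01;kr=0.01"),
  rx("h_hif_deg",   "HIF_VHL",         "VHL",              "mass_action", "kf=0.2"),
  rx("h_hif_nuc",   "HIF",             "HIFn",             "mass_action", "kf=0.02;kr=0.01"),
  rx("h_arnt_bind", "HIFn + ARNT",     "HIF_ARNT",         "mass_action", "kf=0.005;kr=0.01"),
  rx("h_hre_bind",  "HIF_ARNT + HRE",  "HIF_HRE",          "mass_action", "kf=0.02;kr=0.01"),
  rx("h_transcr",   "HIF_HRE",         "HIF_HRE + mRNA",   "mass_action", "kf=2"),
  rx("h_basal_tx",  "",                "mRNA",             "mass_action", "kf=0.0008"),
  rx("h_mrna_deg",  "mRNA",            "",                 "degradation", "k=0.004"),
  rx("h_phd_tx",    "HIF_HRE",         "HIF_HRE + mRNA_PHD","mass_action","kf=2"),
  rx("h_phdmrna_deg","mRNA_PHD",       "",                 "degradation", "k=0.002"),
  rx("h_phd_tl",    "mRNA_PHD",        "mRNA_PHD + PHD",   "mass_action", "kf=0.1"),
  rx("h_phd_deg",   "PHD",             "",                 "degradation", "k=0.001"),
  rx("h_hifn_deg",  "HIFn",            "",                 "degradation", "k=0.005"))

## -------------------------------------------------------------- tumor module
# Dynamic core: VEGF/VEGFR and EGF/EGFR receptor layers, adapters
# (Shc, Grb2-SOS, Gab), Ras-RAF-MEK-ERK with ERK->SOS feedback and
# Akt->RAF crosstalk, PLCgamma/PKC, PI3K-PIP3-Akt with PDK, mTOR/S6K.
# Phosphorylation steps are tagged atp_dependent; K_M,ATP is on the
# micromolar scale (1e5 nM), consistent with kinase ATP Michaelis constants.

KM <- "k_m_atp=1e5"

tumor_dyn <- rbind(
  sp("VEGF",       50,   "tumor"),
  sp("VEGFR",      1000, "tumor"),
  sp("VVEGFR",     30,   "tumor"),
  sp("VVR2",       10,   "tumor"),
  sp("VVR2_P",     3,    "tumor", TRUE, "VVR2"),
  sp("PI3K",       200,  "tumor"),
  sp("VVR_P_PI3K", 10,   "tumor"),
  sp("pPI3K",      20,   "tumor", TRUE, "PI3K"),
  sp("EGF",        8,    "tumor"),
  sp("EGFR",       500,  "tumor"),
  sp("EEGFR",      5,    "tumor"),
  sp("EEGFR_P",    2,    "tumor", TRUE, "EEGFR"),
  sp("EEGFR_Pi",   1,    "tumor"),
  sp("Shc",        300,  "tumor"),
  sp("EEGFR_Shc",  2,    "tumor"),
  sp("pShc",       20,   "tumor", TRUE, "Shc"),
  sp("GS",         100,  "tumor"),
  sp("EEGFR_GS",   2,    "tumor"),
  sp("pShc_GS",    5,    "tumor"),
  sp("GSi",        10,   "tumor"),
  sp("RasGDP",     400,  "tumor"),
  sp("RasGTP",     20,   "tumor"),
  sp("RAF",        200,  "tumor"),
  sp("pRAF",       5,    "tumor", TRUE, "RAF"),
  sp("RAFi",       20,   "tumor"),
  sp("MEK",        500,  "tumor"),
  sp("pMEK",       50,   "tumor", TRUE, "MEK"),
  sp("ERK",        600,  "tumor"),
  sp("pERK",       100,  "tumor", TRUE, "ERK"),
  sp("Rsk",        300,  "tumor"),
  sp("pRsk",       30,   "tumor", TRUE, "Rsk"),
  sp("PLC",        150,  "tumor"),
  sp("EEGFR_PLC",  2,    "tumor"),
  sp("VVR2_PLC",   2,    "tumor"),
  sp("PLCR",       10,   "tumor", TRUE, "PLC"),
  sp("PIP2",       4000, "tumor"),
  sp("DAG",        100,  "tumor"),
  sp("IP3",        50,   "tumor"),
  sp("PKC",        300,  "tumor"),
  sp("DAG_PKC",    20,   "tumor"),
  sp("PIP3",       50,   "tumor"),
  sp("Akt",        250,  "tumor"),
  sp("PIP3_Akt",   20,   "tumor"),
  sp("PDK",        150,  "tumor"),
  sp("PIP3_PDK",   10,   "tumor"),
  sp("pPIP3_Akt",  5,    "tumor", TRUE, "PIP3_Akt"),
  sp("pAkt",       40,   "tumor", TRUE, "Akt"),
  sp("Gab",        120,  "tumor"),
  sp("EEGFR_Gab",  2,    "tumor"),
  sp("pGab",       10,   "tumor", TRUE, "Gab"),
  sp("pGab_PI3K",  5,    "tumor"),
  sp("mTOR",       300,  "tumor"),
  sp("mTORa",      30,   "tumor"),
  sp("S6K",        400,  "tumor"),
  sp("pS6K",       40,   "tumor", TRUE, "S6K"))

tumor_enzymes <- rbind(
  sp("PTEN",   100, "tumor"),
  sp("PP2A",   200, "tumor"),
  sp("MKP3",   80,  "tumor"),
  sp("RasGAP", 120, "tumor"))

tumor_inventory <- c(
  "SOS1", "SOS2", "Grb2", "Shc_p66", "Crk", "Nck", "Gab2", "IRS1", "IRS2",
  "PLCG2", "PKC_delta", "PKC_epsilon", "PKC_zeta", "DGK_alpha", "IP3R",
  "CaM", "CaMKII", "PP2B", "RasGRP1", "RasGRF1", "Rap1", "C3G", "RapGAP",
  "BRAF", "ARAF", "KSR1", "KSR2", "RKIP", "Sprouty1", "Sprouty2", "Spred1",
  "CNK1", "MP1", "MEK2", "MEKK1", "MLK3", "JNK", "p38", "MK2", "Elk1",
  "cFos", "cJun", "cMyc", "CREB", "STAT1", "STAT3", "STAT5", "JAK1",
  "JAK2", "SRC", "FYN", "LYN", "CSK", "PTP1B", "SHP1", "SHP2", "NF1",
  "PI3K_p85", "PI3K_p110b", "PI3K_p110d", "PDK2", "mTORC2", "Rictor",
  "Raptor", "GbL", "TSC1", "TSC2", "Rheb", "AMPK", "LKB1", "PRAS40",
  "FOXO1", "FOXO3", "GSK3a", "GSK3b", "BAD", "MDM2", "p21", "p27",
  "CyclinD1", "CDK4", "RSK2", "RSK3", "S6", "eIF4E", "E4BP1", "PDCD4",
  "SHIP1", "SHIP2", "INPP4B", "PHLPP1", "PHLPP2")
set.seed(7)
tumor_inv_df <- do.call(rbind, lapply(tumor_inventory, function(nm) {
  sp(nm, signif(10^runif(1, 1, 2.7), 3), "tumor")
}))

tumor_species <- rbind(tumor_dyn, tumor_enzymes, tumor_inv_df)

tumor_reactions <- rbind(
  # VEGF / VEGFR layer
  rx("t_vegf_syn",    "",                  "VEGF",            "vegf_synthesis", "k_syn=4"),
  rx("t_vegf_deg",    "VEGF",              "",                "degradation",    "k=0.08"),
  rx("t_vegf_bind",   "VEGF + VEGFR",      "VVEGFR",          "vegf_binding",   "k1f=1e-5;k1r=0.01", target = "VEGF_binding"),
  rx("t_vegfr_syn",   "",                  "VEGFR",           "mass_action",    "kf=1"),
  rx("t_vegfr_deg",   "VEGFR",             "",                "degradation",    "k=0.001"),
  rx("t_vvr_dim",     "2 VVEGFR",          "VVR2",            "mass_action",    "kf=1e-5;kr=0.01"),
  rx("t_vvr2_phos",   "VVR2",              "VVR2_P",          "atp_phospho",    paste0("vmax=10;k_prime=50;", KM), atp = TRUE),
  rx("t_vvr2_dephos", "VVR2_P",            "VVR2",            "mass_action",    "kf=0.05"),
  rx("t_pi3k_bind",   "VVR2_P + PI3K",     "VVR_P_PI3K",      "mass_action",    "kf=2e-4;kr=0.01"),
  rx("t_pi3k_act",    "VVR_P_PI3K",        "VVR2_P + pPI3K",  "atp_phospho",    "vmax=8;k_prime=50;k_m_atp=2e5", atp = TRUE),
  # EGF / EGFR layer
  rx("t_egf_syn",     "",                  "EGF",             "mass_action",    "kf=0.05"),
  rx("t_egf_deg",     "EGF",               "",                "degradation",    "k=0.001"),
  rx("t_egfr_syn",    "",                  "EGFR",            "mass_action",    "kf=0.5"),
  rx("t_egfr_deg",    "EGFR",              "",                "degradation",    "k=0.001"),
  rx("t_egf_bind",    "EGF + EGFR",        "EEGFR",           "mass_action",    "kf=3e-4;kr=0.002"),
  rx("t_eegfr_phos",  "EEGFR",             "EEGFR_P",         "atp_phospho",    paste0("vmax=20;k_prime=100;", KM), atp = TRUE),
  rx("t_eegfr_dephos","EEGFR_P",           "EEGFR",           "mass_action",    "kf=0.05"),
  rx("t_eegfr_int",   "EEGFR_P",           "EEGFR_Pi",        "mass_action",    "kf=2e-4"),
  rx("t_eegfr_rec",   "EEGFR_Pi",          "EGFR",            "mass_action",    "kf=0.005"),
  rx("t_shc_bind",    "EEGFR_P + Shc",     "EEGFR_Shc",       "mass_action",    "kf=3e-4;kr=0.05"),
  rx("t_shc_phos",    "EEGFR_Shc",         "EEGFR_P + pShc",  "atp_phospho",    paste0("vmax=20;k_prime=100;", KM), atp = TRUE),
  rx("t_shc_dephos",  "pShc",              "Shc",             "mass_action",    "kf=0.02"),
  # adapters and Ras
  rx("t_gs_bind_r",   "EEGFR_P + GS",      "EEGFR_GS",        "mass_action",    "kf=3e-4;kr=0.02"),
  rx("t_gs_bind_shc", "pShc + GS",         "pShc_GS",         "mass_action",    "kf=3e-4;kr=0.02"),
  rx("t_ras_act_egfr","RasGDP",            "RasGTP",          "michaelis_menten", "kcat=2;enzyme=EEGFR_GS;km=300"),
  rx("t_ras_act_shc", "RasGDP",            "RasGTP",          "michaelis_menten", "kcat=2;enzyme=pShc_GS;km=300"),
  rx("t_ras_act_vegfr","RasGDP",           "RasGTP",          "michaelis_menten", "kcat=0.05;enzyme=VVR2_P;km=300"),
  rx("t_ras_gap",     "RasGTP",            "RasGDP",          "michaelis_menten", "kcat=3;enzyme=RasGAP;km=200"),
  rx("t_ras_intr",    "RasGTP",            "RasGDP",          "mass_action",    "kf=0.005"),
  rx("t_gs_fb",       "GS",                "GSi",             "michaelis_menten", "kcat=0.05;enzyme=pERK;km=200"),
  rx("t_gs_fb_rev",   "GSi",               "GS",              "mass_action",    "kf=0.05"),
  # RAF / MEK / ERK cascade
  rx("t_raf_act",     "RAF",               "pRAF",            "atp_phospho",    paste0("kcat=0.25;enzyme=RasGTP;k_prime=200;", KM), atp = TRUE, target = "RAF_phospho"),
  rx("t_raf_basal",   "RAF",               "pRAF",            "atp_phospho",    paste0("vmax=0.1;k_prime=200;", KM), atp = TRUE, target = "RAF_phospho"),
  rx("t_raf_dephos",  "pRAF",              "RAF",             "mass_action",    "kf=0.25"),
  rx("t_raf_inh",     "RAF",               "RAFi",            "michaelis_menten", "kcat=0.02;enzyme=pAkt;km=300"),
  rx("t_raf_inh_rev", "RAFi",              "RAF",             "mass_action",    "kf=0.02"),
  rx("t_mek_phos",    "MEK",               "pMEK",            "atp_phospho",    paste0("kcat=1;enzyme=pRAF;k_prime=400;", KM), atp = TRUE, target = "MEK_phospho"),
  rx("t_mek_dephos",  "pMEK",              "MEK",             "michaelis_menten", "kcat=0.2;enzyme=PP2A;km=300"),
  rx("t_erk_phos",    "ERK",               "pERK",            "atp_phospho",    paste0("kcat=1;enzyme=pMEK;k_prime=500;", KM), atp = TRUE),
  rx("t_erk_dephos",  "pERK",              "ERK",             "michaelis_menten", "kcat=0.9;enzyme=MKP3;km=300"),
  rx("t_rsk_phos",    "Rsk",               "pRsk",            "atp_phospho",    paste0("kcat=0.3;enzyme=pERK;k_prime=300;", KM), atp = TRUE),
  rx("t_rsk_dephos",  "pRsk",              "Rsk",             "mass_action",    "kf=0.05"),
  # PLCgamma / PKC
  rx("t_plc_bind",    "EEGFR_P + PLC",     "EEGFR_PLC",       "mass_action",    "kf=3e-4;kr=0.05"),
  rx("t_plc_phos",    "EEGFR_PLC",         "EEGFR_P + PLCR",  "atp_phospho",    paste0("vmax=10;k_prime=100;", KM), atp = TRUE),
  rx("t_plc_vbind",   "VVR2_P + PLC",      "VVR2_PLC",        "mass_action",    "kf=3e-4;kr=0.05"),
  rx("t_plc_vphos",   "VVR2_PLC",          "VVR2_P + PLCR",   "atp_phospho",    paste0("vmax=10;k_prime=100;", KM), atp = TRUE),
  rx("t_plcr_dephos", "PLCR",              "PLC",             "mass_action",    "kf=0.05"),
  rx("t_pip2_hyd",    "PIP2",              "PIP2 + DAG + IP3","michaelis_menten", "kcat=0.01;enzyme=PLCR;km=5000"),
  rx("t_ip3_deg",     "IP3",               "",                "degradation",    "k=0.02"),
  rx("t_dag_deg",     "DAG",               "",                "degradation",    "k=0.02"),
  rx("t_pkc_act",     "DAG + PKC",         "DAG_PKC",         "mass_action",    "kf=1e-4;kr=0.01"),
  rx("t_raf_act_pkc", "RAF",               "pRAF",            "atp_phospho",    paste0("kcat=0.05;enzyme=DAG_PKC;k_prime=200;", KM), atp = TRUE, target = "RAF_phospho"),
  # PI3K / PIP3 / Akt
  rx("t_pi3k_basal",  "PI3K",              "pPI3K",           "atp_phospho",    paste0("vmax=0.5;k_prime=500;", KM), atp = TRUE),
  rx("t_pi3k_deact",  "pPI3K",             "PI3K",            "mass_action",    "kf=0.02"),
  rx("t_gab_bind",    "EEGFR_P + Gab",     "EEGFR_Gab",       "mass_action",    "kf=3e-4;kr=0.05"),
  rx("t_gab_phos",    "EEGFR_Gab",         "EEGFR_P + pGab",  "atp_phospho",    paste0("vmax=10;k_prime=100;", KM), atp = TRUE),
  rx("t_gab_dephos",  "pGab",              "Gab",             "mass_action",    "kf=0.02"),
  rx("t_gabpi3k_bind","pGab + PI3K",       "pGab_PI3K",       "mass_action",    "kf=3e-4;kr=0.02"),
  rx("t_pi3k_act2",   "pGab_PI3K",         "pGab + pPI3K",    "atp_phospho",    "vmax=10;k_prime=50;k_m_atp=2e5", atp = TRUE),
  rx("t_pip3_prod",   "PIP2",              "PIP3",            "michaelis_menten", "kcat=0.5;enzyme=pPI3K;km=4000"),
  rx("t_pip3_pten",   "PIP3",              "PIP2",            "michaelis_menten", "kcat=1;enzyme=PTEN;km=400"),
  rx("t_pip3_akt",    "PIP3 + Akt",        "PIP3_Akt",        "mass_action",    "kf=1e-4;kr=0.01"),
  rx("t_pip3_pdk",    "PIP3 + PDK",        "PIP3_PDK",        "mass_action",    "kf=1e-4;kr=0.01"),
  rx("t_akt_phos",    "PIP3_Akt",          "pPIP3_Akt",       "atp_phospho",    "kcat=1;enzyme=PIP3_PDK;k_prime=100;k_m_atp=6e5", atp = TRUE, target = "AKT_phospho"),
  rx("t_pakt_rel",    "pPIP3_Akt",         "pAkt + PIP3",     "mass_action",    "kf=0.05;kr=1e-4"),
  rx("t_pakt_dephos", "pAkt",              "Akt",             "michaelis_menten", "kcat=0.08;enzyme=PP2A;km=300"),
  rx("t_ppakt_dephos","pPIP3_Akt",         "PIP3_Akt",        "mass_action",    "kf=0.005"),
  # mTOR / S6K
  rx("t_mtor_act",    "mTOR",              "mTORa",           "atp_phospho",    paste0("kcat=0.05;enzyme=pAkt;k_prime=300;", KM), atp = TRUE),
  rx("t_mtor_deact",  "mTORa",             "mTOR",            "mass_action",    "kf=0.02"),
  rx("t_s6k_phos",    "S6K",               "pS6K",            "atp_phospho",    paste0("kcat=0.2;enzyme=mTORa;k_prime=300;", KM), atp = TRUE),
  rx("t_s6k_dephos",  "pS6K",              "S6K",             "mass_action",    "kf=0.05"))

## ------------------------------------------------------------------- output
stopifnot(nrow(hif_species) + nrow(tumor_species) == 189,
          nrow(hif_reactions) + nrow(tumor_reactions) == 86,
          !anyDuplicated(c(hif_species$id, tumor_species$id)),
          !anyDuplicated(c(hif_reactions$id, tumor_reactions$id)))

out <- file.path("inst", "extdata", "model")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wr <- function(df, nm) {
  utils::write.table(df, file.path(out, nm), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
wr(hif_species,     "species_hif_synthetic.tsv")
wr(hif_reactions,   "reactions_hif_synthetic.tsv")
wr(tumor_species,   "species_tumor_synthetic.tsv")
wr(tumor_reactions, "reactions_tumor_synthetic.tsv")
cat(sprintf("wrote tables: %d species, %d reactions\n",
            nrow(hif_species) + nrow(tumor_species),
            nrow(hif_reactions) + nrow(tumor_reactions)))
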