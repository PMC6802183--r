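id	reactants	products	rate_law	params	atp_dependent	drug_target	provenance
h_hif_syn		HIF	mass_action	kf=0.4	FALSE		reconstructed
h_hif_ohase	HIF + PHD + O2	HIF_OH + PHD + O2	mass_action	kf=0.5	FALSE		reconstructed
h_vhl_bind	HIF_OH + VHL	HIF_VHL	mass_action	kf=0.01;kr=0.01	FALSE		reconstructed
h_hif_deg	HIF_VHL	VHL	mass_action	kf=0.2	FALSE		reconstructed
h_hif_nuc	HIF	HIFn	mass_action	kf=0.02;kr=0.01	FALSE		reconstructed
h_arnt_bind	HIFn + ARNT	HIF_ARNT	mass_action	kf=0.005;kr=0.01	FALSE		reconstructed
h_hre_bind	HIF_ARNT + HRE	HIF_HRE	mass_action	kf=0.02;kr=0.01	FALSE		reconstructed
h_transcr	HIF_HRE	HIF_HRE + mRNA	mass_action	kf=2	FALSE		reconstructed
h_basal_tx		mRNA	mass_action	kf=0.0008	FALSE		reconstructed
h_mrna_deg	mRNA		degradation	k=0.004	FALSE		reconstructed
h_phd_tx	HIF_HRE	HIF_HRE + mRNA_PHD	mass_action	kf=2	FALSE		reconstructed
h_phdmrna_deg	mRNA_PHD		degradation	k=0.002	FALSE		reconstructed
h_phd_tl	mRNA_PHD	mRNA_PHD + PHD	mass_action	kf=0.1	FALSE		reconstructed
h_phd_deg	PHD		degradation	k=0.001	FALSE		reconstructed
h_hifn_deg	HIFn		degradation	k=0.005	FALSE		reconstructed
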