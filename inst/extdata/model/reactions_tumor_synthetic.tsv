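id	reactants	products	rate_law	params	atp_dependent	drug_target	provenance
t_vegf_syn		VEGF	vegf_synthesis	k_syn=4	FALSE		reconstructed
t_vegf_deg	VEGF		degradation	k=0.08	FALSE		reconstructed
t_vegf_bind	VEGF + VEGFR	VVEGFR	vegf_binding	k1f=1e-5;k1r=0.01	FALSE	VEGF_binding	reconstructed
t_vegfr_syn		VEGFR	mass_action	kf=1	FALSE		reconstructed
t_vegfr_deg	VEGFR		degradation	k=0.001	FALSE		reconstructed
t_vvr_dim	2 VVEGFR	VVR2	mass_action	kf=1e-5;kr=0.01	FALSE		reconstructed
t_vvr2_phos	VVR2	VVR2_P	atp_phospho	vmax=10;k_prime=50;k_m_atp=1e5	TRUE		reconstructed
t_vvr2_dephos	VVR2_P	VVR2	mass_action	kf=0.05	FALSE		reconstructed
t_pi3k_bind	VVR2_P + PI3K	VVR_P_PI3K	mass_action	kf=2e-4;kr=0.01	FALSE		reconstructed
t_pi3k_act	VVR_P_PI3K	VVR2_P + pPI3K	atp_phospho	vmax=8;k_prime=50;k_m_atp=2e5	TRUE		reconstructed
t_egf_syn		EGF	mass_action	kf=0.05	FALSE		reconstructed
t_egf_deg	EGF		degradation	k=0.001	FALSE		reconstructed
t_egfr_syn		EGFR	mass_action	kf=0.5	FALSE		reconstructed
t_egfr_deg	EGFR		degradation	k=0.001	FALSE		reconstructed
t_egf_bind	EGF + EGFR	EEGFR	mass_action	kf=3e-4;kr=0.002	FALSE		reconstructed
t_eegfr_phos	EEGFR	EEGFR_P	atp_phospho	vmax=20;k_prime=100;k_m_atp=1e5	TRUE		reconstructed
t_eegfr_dephos	EEGFR_P	EEGFR	mass_action	kf=0.05	FALSE		reconstructed
t_eegfr_int	EEGFR_P	EEGFR_Pi	mass_action	kf=2e-4	FALSE		reconstructed
t_eegfr_rec	EEGFR_Pi	EGFR	mass_action	kf=0.005	FALSE		reconstructed
t_shc_bind	EEGFR_P + Shc	EEGFR_Shc	mass_action	kf=3e-4;kr=0.05	FALSE		reconstructed
t_shc_phos	EEGFR_Shc	EEGFR_P + pShc	atp_phospho	vmax=20;k_prime=100;k_m_atp=1e5	TRUE		reconstructed
t_shc_dephos	pShc	Shc	mass_action	kf=0.02	FALSE		reconstructed
t_gs_bind_r	EEGFR_P + GS	EEGFR_GS	mass_action	kf=3e-4;kr=0.02	FALSE		reconstructed
t_gs_bind_shc	pShc + GS	pShc_GS	mass_action	kf=3e-4;kr=0.02	FALSE		reconstructed
t_ras_act_egfr	RasGDP	RasGTP	michaelis_menten	kcat=2;enzyme=EEGFR_GS;km=300	FALSE		reconstructed
t_ras_act_shc	RasGDP	RasGTP	michaelis_menten	kcat=2;enzyme=pShc_GS;km=300	FALSE		reconstructed
t_ras_act_vegfr	RasGDP	RasGTP	michaelis_menten	kcat=0.05;enzyme=VVR2_P;km=300	FALSE		reconstructed
t_ras_gap	RasGTP	RasGDP	michaelis_menten	kcat=3;enzyme=RasGAP;km=200	FALSE		reconstructed
t_ras_intr	RasGTP	RasGDP	mass_action	kf=0.005	FALSE		reconstructed
t_gs_fb	GS	GSi	michaelis_menten	kcat=0.05;enzyme=pERK;km=200	FALSE		reconstructed
t_gs_fb_rev	GSi	GS	mass_action	kf=0.05	FALSE		reconstructed
t_raf_act	RAF	pRAF	atp_phospho	kcat=0.25;enzyme=RasGTP;k_prime=200;k_m_atp=1e5	TRUE	RAF_phospho	reconstructed
t_raf_basal	RAF	pRAF	atp_phospho	vmax=0.1;k_prime=200;k_m_atp=1e5	TRUE	RAF_phospho	reconstructed
t_raf_dephos	pRAF	RAF	mass_action	kf=0.25	FALSE		reconstructed
t_raf_inh	RAF	RAFi	michaelis_menten	kcat=0.02;enzyme=pAkt;km=300	FALSE		reconstructed
t_raf_inh_rev	RAFi	RAF	mass_action	kf=0.02	FALSE		reconstructed
t_mek_phos	MEK	pMEK	atp_phospho	kcat=1;enzyme=pRAF;k_prime=400;k_m_atp=1e5	TRUE	MEK_phospho	reconstructed
t_mek_dephos	pMEK	MEK	michaelis_menten	kcat=0.2;enzyme=PP2A;km=300	FALSE		reconstructed
t_erk_phos	ERK	pERK	atp_phospho	kcat=1;enzyme=pMEK;k_prime=500;k_m_atp=1e5	TRUE		reconstructed
t_erk_dephos	pERK	ERK	michaelis_menten	kcat=0.9;enzyme=MKP3;km=300	FALSE		reconstructed
t_rsk_phos	Rsk	pRsk	atp_phospho	kcat=0.3;enzyme=pERK;k_prime=300;k_m_atp=1e5	TRUE		reconstructed
t_rsk_dephos	pRsk	Rsk	mass_action	kf=0.05	FALSE		reconstructed
t_plc_bind	EEGFR_P + PLC	EEGFR_PLC	mass_action	kf=3e-4;kr=0.05	FALSE		reconstructed
t_plc_phos	EEGFR_PLC	EEGFR_P + PLCR	atp_phospho	vmax=10;k_prime=100;k_m_atp=1e5	TRUE		reconstructed
t_plc_vbind	VVR2_P + PLC	VVR2_PLC	mass_action	kf=3e-4;kr=0.05	FALSE		reconstructed
t_plc_vphos	VVR2_PLC	VVR2_P + PLCR	atp_phospho	vmax=10;k_prime=100;k_m_atp=1e5	TRUE		reconstructed
t_plcr_dephos	PLCR	PLC	mass_action	kf=0.05	FALSE		reconstructed
t_pip2_hyd	PIP2	PIP2 + DAG + IP3	michaelis_menten	kcat=0.01;enzyme=PLCR;km=5000	FALSE		reconstructed
t_ip3_deg	IP3		degradation	k=0.02	FALSE		reconstructed
t_dag_deg	DAG		degradation	k=0.02	FALSE		reconstructed
t_pkc_act	DAG + PKC	DAG_PKC	mass_action	kf=1e-4;kr=0.01	FALSE		reconstructed
t_raf_act_pkc	RAF	pRAF	atp_phospho	kcat=0.05;enzyme=DAG_PKC;k_prime=200;k_m_atp=1e5	TRUE	RAF_phospho	reconstructed
t_pi3k_basal	PI3K	pPI3K	atp_phospho	vmax=0.5;k_prime=500;k_m_atp=1e5	TRUE		reconstructed
t_pi3k_deact	pPI3K	PI3K	mass_action	kf=0.02	FALSE		reconstructed
t_gab_bind	EEGFR_P + Gab	EEGFR_Gab	mass_action	kf=3e-4;kr=0.05	FALSE		reconstructed
t_gab_phos	EEGFR_Gab	EEGFR_P + pGab	atp_phospho	vmax=10;k_prime=100;k_m_atp=1e5	TRUE		reconstructed
t_gab_dephos	pGab	Gab	mass_action	kf=0.02	FALSE		reconstructed
t_gabpi3k_bind	pGab + PI3K	pGab_PI3K	mass_action	kf=3e-4;kr=0.02	FALSE		reconstructed
t_pi3k_act2	pGab_PI3K	pGab + pPI3K	atp_phospho	vmax=10;k_prime=50;k_m_atp=2e5	TRUE		reconstructed
t_pip3_prod	PIP2	PIP3	michaelis_menten	kcat=0.5;enzyme=pPI3K;km=4000	FALSE		reconstructed
t_pip3_pten	PIP3	PIP2	michaelis_menten	kcat=1;enzyme=PTEN;km=400	FALSE		reconstructed
t_pip3_akt	PIP3 + Akt	PIP3_Akt	mass_action	kf=1e-4;kr=0.01	FALSE		reconstructed
t_pip3_pdk	PIP3 + PDK	PIP3_PDK	mass_action	kf=1e-4;kr=0.01	FALSE		reconstructed
t_akt_phos	PIP3_Akt	pPIP3_Akt	atp_phospho	kcat=1;enzyme=PIP3_PDK;k_prime=100;k_m_atp=6e5	TRUE	AKT_phospho	reconstructed
t_pakt_rel	pPIP3_Akt	pAkt + PIP3	mass_action	kf=0.05;kr=1e-4	FALSE		reconstructed
t_pakt_dephos	pAkt	Akt	michaelis_menten	kcat=0.08;enzyme=PP2A;km=300	FALSE		reconstructed
t_ppakt_dephos	pPIP3_Akt	PIP3_Akt	mass_action	kf=0.005	FALSE		reconstructed
t_mtor_act	mTOR	mTORa	atp_phospho	kcat=0.05;enzyme=pAkt;k_prime=300;k_m_atp=1e5	TRUE		reconstructed
t_mtor_deact	mTORa	mTOR	mass_action	kf=0.02	FALSE		reconstructed
t_s6k_phos	S6K	pS6K	atp_phospho	kcat=0.2;enzyme=mTORa;k_prime=300;k_m_atp=1e5	TRUE		reconstructed
t_s6k_dephos	pS6K	S6K	mass_action	kf=0.05	FALSE		reconstructed
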