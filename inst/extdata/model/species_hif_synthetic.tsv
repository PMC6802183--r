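id	initial_conc	unit	module	is_phospho_form	phospho_pair	provenance
O2	1	fraction	hif	FALSE		reconstructed
HIF	1	nM	hif	FALSE		reconstructed
PHD	100	nM	hif	FALSE		reconstructed
HIF_OH	0.1	nM	hif	FALSE		reconstructed
VHL	100	nM	hif	FALSE		reconstructed
HIF_VHL	0.1	nM	hif	FALSE		reconstructed
HIFn	0.5	nM	hif	FALSE		reconstructed
ARNT	100	nM	hif	FALSE		reconstructed
HIF_ARNT	0.5	nM	hif	FALSE		reconstructed
HRE	0.1	nM	hif	FALSE		reconstructed
HIF_HRE	0.01	nM	hif	FALSE		reconstructed
mRNA	1	nM	hif	FALSE		reconstructed
mRNA_PHD	1	nM	hif	FALSE		reconstructed
PHD1	236	nM	hif	FALSE		reconstructed
PHD3	254	nM	hif	FALSE		reconstructed
FIH	26.9	nM	hif	FALSE		reconstructed
p300	176	nM	hif	FALSE		reconstructed
CBP	91.8	nM	hif	FALSE		reconstructed
ElonginB	60.1	nM	hif	FALSE		reconstructed
ElonginC	127	nM	hif	FALSE		reconstructed
Cul2	15.9	nM	hif	FALSE		reconstructed
Rbx1	96.7	nM	hif	FALSE		reconstructed
Ub_pool	114	nM	hif	FALSE		reconstructed
Proteasome26S	48.6	nM	hif	FALSE		reconstructed
Importin	120	nM	hif	FALSE		reconstructed
CRM1	252	nM	hif	FALSE		reconstructed
HSP90	24.2	nM	hif	FALSE		reconstructed
RACK1	49.4	nM	hif	FALSE		reconstructed
OS9	257	nM	hif	FALSE		reconstructed
ARD1	293	nM	hif	FALSE		reconstructed
VDU2	15	nM	hif	FALSE		reconstructed
Siah2	51.6	nM	hif	FALSE		reconstructed
HAF	69.3	nM	hif	FALSE		reconstructed
Hsp70	227	nM	hif	FALSE		reconstructed
CHIP	16.1	nM	hif	FALSE		reconstructed
Morg1	304	nM	hif	FALSE		reconstructed
Mint3	263	nM	hif	FALSE		reconstructed
Cited2	13.3	nM	hif	FALSE		reconstructed
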