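id	initial_conc	unit	module	is_phospho_form	phospho_pair	provenance
VEGF	50	nM	tumor	FALSE		reconstructed
VEGFR	1000	nM	tumor	FALSE		reconstructed
VVEGFR	30	nM	tumor	FALSE		reconstructed
VVR2	10	nM	tumor	FALSE		reconstructed
VVR2_P	3	nM	tumor	TRUE	VVR2	reconstructed
PI3K	200	nM	tumor	FALSE		reconstructed
VVR_P_PI3K	10	nM	tumor	FALSE		reconstructed
pPI3K	20	nM	tumor	TRUE	PI3K	reconstructed
EGF	8	nM	tumor	FALSE		reconstructed
EGFR	500	nM	tumor	FALSE		reconstructed
EEGFR	5	nM	tumor	FALSE		reconstructed
EEGFR_P	2	nM	tumor	TRUE	EEGFR	reconstructed
EEGFR_Pi	1	nM	tumor	FALSE		reconstructed
Shc	300	nM	tumor	FALSE		reconstructed
EEGFR_Shc	2	nM	tumor	FALSE		reconstructed
pShc	20	nM	tumor	TRUE	Shc	reconstructed
GS	100	nM	tumor	FALSE		reconstructed
EEGFR_GS	2	nM	tumor	FALSE		reconstructed
pShc_GS	5	nM	tumor	FALSE		reconstructed
GSi	10	nM	tumor	FALSE		reconstructed
RasGDP	400	nM	tumor	FALSE		reconstructed
RasGTP	20	nM	tumor	FALSE		reconstructed
RAF	200	nM	tumor	FALSE		reconstructed
pRAF	5	nM	tumor	TRUE	RAF	reconstructed
RAFi	20	nM	tumor	FALSE		reconstructed
MEK	500	nM	tumor	FALSE		reconstructed
pMEK	50	nM	tumor	TRUE	MEK	reconstructed
ERK	600	nM	tumor	FALSE		reconstructed
pERK	100	nM	tumor	TRUE	ERK	reconstructed
Rsk	300	nM	tumor	FALSE		reconstructed
pRsk	30	nM	tumor	TRUE	Rsk	reconstructed
PLC	150	nM	tumor	FALSE		reconstructed
EEGFR_PLC	2	nM	tumor	FALSE		reconstructed
VVR2_PLC	2	nM	tumor	FALSE		reconstructed
PLCR	10	nM	tumor	TRUE	PLC	reconstructed
PIP2	4000	nM	tumor	FALSE		reconstructed
DAG	100	nM	tumor	FALSE		reconstructed
IP3	50	nM	tumor	FALSE		reconstructed
PKC	300	nM	tumor	FALSE		reconstructed
DAG_PKC	20	nM	tumor	FALSE		reconstructed
PIP3	50	nM	tumor	FALSE		reconstructed
Akt	250	nM	tumor	FALSE		reconstructed
PIP3_Akt	20	nM	tumor	FALSE		reconstructed
PDK	150	nM	tumor	FALSE		reconstructed
PIP3_PDK	10	nM	tumor	FALSE		reconstructed
pPIP3_Akt	5	nM	tumor	TRUE	PIP3_Akt	reconstructed
pAkt	40	nM	tumor	TRUE	Akt	reconstructed
Gab	120	nM	tumor	FALSE		reconstructed
EEGFR_Gab	2	nM	tumor	FALSE		reconstructed
pGab	10	nM	tumor	TRUE	Gab	reconstructed
pGab_PI3K	5	nM	tumor	FALSE		reconstructed
mTOR	300	nM	tumor	FALSE		reconstructed
mTORa	30	nM	tumor	FALSE		reconstructed
S6K	400	nM	tumor	FALSE		reconstructed
pS6K	40	nM	tumor	TRUE	S6K	reconstructed
PTEN	100	nM	tumor	FALSE		reconstructed
PP2A	200	nM	tumor	FALSE		reconstructed
MKP3	80	nM	tumor	FALSE		reconstructed
RasGAP	120	nM	tumor	FALSE		reconstructed
SOS1	480	nM	tumor	FALSE		reconstructed
SOS2	47.4	nM	tumor	FALSE		reconstructed
Grb2	15.7	nM	tumor	FALSE		reconstructed
Shc_p66	13.1	nM	tumor	FALSE		reconstructed
Crk	26	nM	tumor	FALSE		reconstructed
Nck	222	nM	tumor	FALSE		reconstructed
Gab2	37.9	nM	tumor	FALSE		reconstructed
IRS1	449	nM	tumor	FALSE		reconstructed
IRS2	19.1	nM	tumor	FALSE		reconstructed
PLCG2	60.3	nM	tumor	FALSE		reconstructed
PKC_delta	19.6	nM	tumor	FALSE		reconstructed
PKC_epsilon	24.7	nM	tumor	FALSE		reconstructed
PKC_zeta	206	nM	tumor	FALSE		reconstructed
DGK_alpha	14.6	nM	tumor	FALSE		reconstructed
IP3R	59	nM	tumor	FALSE		reconstructed
CaM	13.9	nM	tumor	FALSE		reconstructed
CaMKII	89.8	nM	tumor	FALSE		reconstructed
PP2B	10.3	nM	tumor	FALSE		reconstructed
RasGRP1	474	nM	tumor	FALSE		reconstructed
RasGRF1	34.5	nM	tumor	FALSE		reconstructed
Rap1	122	nM	tumor	FALSE		reconstructed
C3G	31.8	nM	tumor	FALSE		reconstructed
RapGAP	495	nM	tumor	FALSE		reconstructed
BRAF	347	nM	tumor	FALSE		reconstructed
ARAF	480	nM	tumor	FALSE		reconstructed
KSR1	12.9	nM	tumor	FALSE		reconstructed
KSR2	116	nM	tumor	FALSE		reconstructed
RKIP	68.2	nM	tumor	FALSE		reconstructed
Sprouty1	447	nM	tumor	FALSE		reconstructed
Sprouty2	41.3	nM	tumor	FALSE		reconstructed
Spred1	143	nM	tumor	FALSE		reconstructed
CNK1	28.1	nM	tumor	FALSE		reconstructed
MP1	20.7	nM	tumor	FALSE		reconstructed
MEK2	20.6	nM	tumor	FALSE		reconstructed
MEKK1	44.1	nM	tumor	FALSE		reconstructed
MLK3	275	nM	tumor	FALSE		reconstructed
JNK	70.3	nM	tumor	FALSE		reconstructed
p38	221	nM	tumor	FALSE		reconstructed
MK2	266	nM	tumor	FALSE		reconstructed
Elk1	59.8	nM	tumor	FALSE		reconstructed
cFos	229	nM	tumor	FALSE		reconstructed
cJun	44.6	nM	tumor	FALSE		reconstructed
cMyc	196	nM	tumor	FALSE		reconstructed
CREB	55.3	nM	tumor	FALSE		reconstructed
STAT1	344	nM	tumor	FALSE		reconstructed
STAT3	34.9	nM	tumor	FALSE		reconstructed
STAT5	13.8	nM	tumor	FALSE		reconstructed
JAK1	244	nM	tumor	FALSE		reconstructed
JAK2	337	nM	tumor	FALSE		reconstructed
SRC	440	nM	tumor	FALSE		reconstructed
FYN	94.2	nM	tumor	FALSE		reconstructed
LYN	168	nM	tumor	FALSE		reconstructed
CSK	207	nM	tumor	FALSE		reconstructed
PTP1B	117	nM	tumor	FALSE		reconstructed
SHP1	169	nM	tumor	FALSE		reconstructed
SHP2	45.5	nM	tumor	FALSE		reconstructed
NF1	18.9	nM	tumor	FALSE		reconstructed
PI3K_p85	20.8	nM	tumor	FALSE		reconstructed
PI3K_p110b	46.3	nM	tumor	FALSE		reconstructed
PI3K_p110d	29.2	nM	tumor	FALSE		reconstructed
PDK2	21.2	nM	tumor	FALSE		reconstructed
mTORC2	72	nM	tumor	FALSE		reconstructed
Rictor	199	nM	tumor	FALSE		reconstructed
Raptor	151	nM	tumor	FALSE		reconstructed
GbL	84.1	nM	tumor	FALSE		reconstructed
TSC1	132	nM	tumor	FALSE		reconstructed
TSC2	62.6	nM	tumor	FALSE		reconstructed
Rheb	65.9	nM	tumor	FALSE		reconstructed
AMPK	37.4	nM	tumor	FALSE		reconstructed
LKB1	52.7	nM	tumor	FALSE		reconstructed
PRAS40	30.8	nM	tumor	FALSE		reconstructed
FOXO1	105	nM	tumor	FALSE		reconstructed
FOXO3	269	nM	tumor	FALSE		reconstructed
GSK3a	114	nM	tumor	FALSE		reconstructed
GSK3b	16.9	nM	tumor	FALSE		reconstructed
BAD	92.3	nM	tumor	FALSE		reconstructed
MDM2	56.7	nM	tumor	FALSE		reconstructed
p21	55.5	nM	tumor	FALSE		reconstructed
p27	115	nM	tumor	FALSE		reconstructed
CyclinD1	385	nM	tumor	FALSE		reconstructed
CDK4	324	nM	tumor	FALSE		reconstructed
RSK2	312	nM	tumor	FALSE		reconstructed
RSK3	25.8	nM	tumor	FALSE		reconstructed
S6	182	nM	tumor	FALSE		reconstructed
eIF4E	45.6	nM	tumor	FALSE		reconstructed
E4BP1	13.6	nM	tumor	FALSE		reconstructed
PDCD4	14.5	nM	tumor	FALSE		reconstructed
SHIP1	198	nM	tumor	FALSE		reconstructed
SHIP2	39	nM	tumor	FALSE		reconstructed
INPP4B	51.1	nM	tumor	FALSE		reconstructed
PHLPP1	38.4	nM	tumor	FALSE		reconstructed
PHLPP2	10.3	nM	tumor	FALSE		reconstructed
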