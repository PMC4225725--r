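# SYNTHETIC RECONSTRUCTION of a genome-scale plant TF/TR/CR rule set.
# 108 families assembled from the plant gene-regulation literature
# (plant transcription-factor database family rosters and published
# family/domain characterizations). Domain logics are written in this
# package's rule language; accession choices for the well-studied
# families follow the published characterizations, while those for the
# less common families are the curator's best effort (approximate) and
# should be reviewed before production use. This file demonstrates
# full-scale loading and classification; it is NOT a published curation.
# Columns: family, category, must_have, prohibited ("-" = none).
family	category	must_have	prohibited
AP2-EREBP	TF	IPR001471	IPR003340
ARF	TF	(IPR010525|IPR011525)&IPR003340	-
ARID	TF	IPR001606	-
AS2-LOB	TF	IPR004883	-
B3	TF	IPR003340	IPR001471|IPR010525|IPR011525
BBR-BPC	TF	PF06217	-
BES1	TF	PF05687	-
bHLH	TF	IPR011598	-
bZIP	TF	IPR004827	-
C2C2-CO-like	TF	IPR000315&IPR010402	-
C2C2-Dof	TF	IPR003851	-
C2C2-GATA	TF	IPR000679	-
C2C2-LSD	TF	PF06943	-
C2C2-YABBY	TF	IPR006780	-
C2H2	TF	IPR007087	-
C3H	TF	IPR000571	-
CAMTA	TF	IPR005559	-
CPP	TF	IPR005172	-
CSD	TF	IPR011129	-
DBP	TF	PF08780	-
E2F-DP	TF	IPR003316	-
EIL	TF	IPR006957	-
FHA	TF	IPR000253	-
G2-like	TF	IPR006447	IPR001789
GARP-ARR-B	TF	IPR006447&IPR001789	-
GeBP	TF	PF04504	-
GRAS	TF	IPR005202	-
GRF	TF	IPR014978&IPR014977	-
HB	TF	IPR001356	IPR003106
HD-Zip	TF	IPR001356&IPR003106	-
HRT-like	TF	PF04770	-
HSF	TF	IPR000232	-
LFY	TF	IPR002910	-
LIM	TF	IPR001781	-
MADS type1	TF	IPR002100	IPR002487
MADS-MICK	TF	IPR002100&IPR002487	-
MYB	TF	IPR001005	-
MYB-related	TF	IPR017930	IPR001005
NAC	TF	IPR003441	-
NF-YA	TF	IPR001289	-
NF-YB	TF	IPR003958	-
NF-YC	TF	IPR003956	-
Nin-like	TF	IPR003035	-
OFP	TF	PF04844	-
PLATZ	TF	PF04640	-
RAV	TF	IPR003340&IPR001471	IPR010525|IPR011525
S1Fa-like	TF	PF04689	-
SAP	TF	PF02037	-
SBP	TF	IPR004333	-
SRS	TF	PF05142	-
TCP	TF	IPR005333	-
Tify	TF	IPR010399	-
Trihelix	TF	PF13837	-
TUB	TF	IPR000007	-
ULT	TF	PF11779	-
VOZ	TF	PF16524	-
Whirly	TF	IPR013742	-
WRKY	TF	IPR003657	-
zf-HD	TF	IPR006456	-
BSD	TF	PF03909	-
Alfin-like	TR	PF17919	-
Aux-IAA	TR	IPR003311	IPR010525|IPR011525
BTB-POZ	TR	PS50097|SM00225	IPR002083|IPR002110
BTB-POZ-MATH	TR	(PS50097|SM00225)&IPR002083	-
ABTB	TR	(PS50097|SM00225)&IPR002110	-
TAZ	TR	IPR000197	-
GNAT	TR	IPR000182	-
HMG	TR	IPR000910	-
SET	TR	IPR001214	PF11616
TRAF	TR	IPR008974	PS50097|SM00225
LUG	TR	PF08513	-
mTERF	TR	PF02536	-
Sigma70-like	TR	IPR000943	-
Pseudo-ARR-B	TR	IPR001789&IPR010402	-
DDT	TR	IPR004022	-
GIF	TR	IPR007726	-
IWS1	TR	PF08711	-
MBF1	TR	IPR013729	-
MED6	TR	PF04934	-
MED7	TR	PF05983	-
SOH1	TR	PF05669	-
TFb2	TR	PF03849	-
Rcd1-like	TR	IPR007216	-
CCAAT-DR1	TR	PF00808	IPR003958|IPR003956
NOT2	TR	PF04153	-
PHD	TR	IPR001965	PF17919
CHROMO-DOMAIN	CR	PS50013|SM00298	IPR000330
CHD	CR	(PS50013|SM00298)&IPR000330	-
SNF2	CR	IPR000330	PS50013|SM00298
HDAC	CR	IPR000286	-
HD2	CR	PF10502	-
SIR2	CR	IPR003000	-
HAC	CR	PF08214	-
MYST-HAT	CR	IPR002717	-
DNMT	CR	IPR001525	-
PRMT	CR	PF05185	-
Bromodomain	CR	IPR001487	-
Jumonji	CR	IPR003347|IPR003349	-
PcG-EZ	CR	IPR001214&PF11616	-
PcG-VEFS	CR	PF09733	-
PcG-FIE	CR	PF12894	-
SWI-SNF-BAF60b	CR	PF02201	-
SWI-SNF-SWI3	CR	PF04433	-
HIRA	CR	PF07569	-
Argonaute	CR	IPR003100&IPR003165	-
HUB	CR	PF13923	-
FACT-SSRP	CR	PF08512	-
FACT-SPT16	CR	PF08644	-
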