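name	organism	source	variant	uniprot_id	subtype	primary_pattern	less_preferred	structure_ids
SpCas9	S. pyogenes	natural	-	Q99ZW2	II-A	NGG	NAG;NGA	4UN3;5Y36;5FQ5
SpCas9-VQR	S. pyogenes	engineered	VQR	-	II-A	NGA	-	5B2R
SpCas9-VRER	S. pyogenes	engineered	VRER	-	II-A	NGCG	-	5B2T;5FW3
SpCas9-EQR	S. pyogenes	engineered	EQR	-	II-A	NGAG	-	5B2S;5FW2
SpCas9-NG	S. pyogenes	engineered	NG	-	II-A	NG	-	6AI6
SpCas9-NRRH	S. pyogenes	engineered	NRRH	-	II-A	NRRH	-	-
SpCas9-NRCH	S. pyogenes	engineered	NRCH	-	II-A	NRCH	-	-
SpCas9-NRTH	S. pyogenes	engineered	NRTH	-	II-A	NRTH	-	-
xCas9	S. pyogenes	engineered	xCas9	-	II-A	NGN	-	6K4P;6K4Q;6K4S;6K4U;6AEB;6AEG
SaCas9	S. aureus	natural	-	J7RUA5	II-A	NNGRRT	-	5AXW;5CZZ
SaCas9-KKH	S. aureus	engineered	KKH	-	II-A	NNNRRT	-	-
St1Cas9	S. thermophilus	natural	-	Q03JI6	II-A	NNRGAAW	NNGGAAW;NNGATAG;NNTCTTA;NNCAATA	-
St3Cas9	S. thermophilus	natural	-	G3ECR1	II-A	NGGNG	-	-
SpasCas9	S. pasteurianus	natural	-	F5X275	II-A	NNGTGA	-	-
TdCas9	T. denticola	natural	-	Q73QW6	II-A	NAAAAC	-	-
Nme1Cas9	N. meningitidis	natural	-	C9X1G5	II-C	NNNNGATT	-	6JDV;6KC8
Nme2Cas9	N. meningitidis	natural	-	A1IQ68	II-C	NHDTCCA	-	6JFU;6JE3
CjCas9	C. jejuni	natural	-	Q0P897	II-C	NNNVRYM	-	5X2H;5X2G
AceCas9	A. cellulolyticus	natural	-	A0LWB3	II-C	NNNCC	-	6WBR;6WC0
FnCas9	F. novicida	natural	-	A0Q5Y3	II-B	NGG	NAG;NGA	5B2O;5B2P
FnCas9-RHA	F. novicida	engineered	RHA	-	II-B	YG	-	5B2Q
FnCas12a	F. novicida	natural	-	A0Q7Q2	V-A	TTV	-	-
AsCas12a	Acidaminococcus sp.	natural	-	U2UMQ6	V-A	TTTN	VTTV;YCCA;TCTV;TTCV;GTTV;GCTV	5B43
AsCas12a-RVR	Acidaminococcus sp.	engineered	RVR	-	V-A	TATV	-	5XH6
AsCas12a-RR	Acidaminococcus sp.	engineered	RR	-	V-A	TYCV	-	5XH7
enAsCas12a-TGTV	Acidaminococcus sp.	engineered	TGTV	-	V-A	TGTV	-	-
enAsCas12a-VTTV	Acidaminococcus sp.	engineered	VTTV	-	V-A	VTTV	-	-
enAsCas12a-TTTT	Acidaminococcus sp.	engineered	TTTT	-	V-A	TTTT	-	-
enAsCas12a-TTCN	Acidaminococcus sp.	engineered	TTCN	-	V-A	TTCN	-	-
AsCas12a-RVRm	Acidaminococcus sp.	engineered	RVRm	-	V-A	TATG	-	-
LbCas12a	L. bacterium	natural	-	A0A5S8WF58	V-A	TTTN	TCTA;TCCA;CCCA	5XUS;5XUT;5XUU;5XUZ
MbCas12a	M. bovoculi	natural	-	A0A3F3CDD6	V	TTTN	-	-
AacCas12b	A. acidoterrestris	natural	-	T0D7A2	V-B	DTTD	-	-
BthCas12b	Brevibacillus sp.	natural	-	A0A9X7XSH8	V-B	ATTN	-	-
DpbCas12e	Deltaproteobacteria	natural	-	A0A357BT59	V-E	TTCN	-	-
Cas12e	Planctomycetes	natural	-	A0A1G3BXR9	V-E	TTCN	-	-
Cas14a1	uncultured archaeon	natural	-	A0A482D308	V-F	TTTR	YTCA	7L49;7C7L
Cas12c1	P. muris	natural	-	A0A9X9ZA50	V-C	TG	-	7VYX
Cas12c2	P. muris	natural	-	-	V-C	TN	-	7V94
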