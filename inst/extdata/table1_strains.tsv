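gene	protein	modification	background	database_id	delta_sac	thrombosis	bleeding	remarks
Ano1	Anoctamin-1	PF4-Cre Ano1	C57Bl/6	07	o	nd	nd	-
Ano6	Anoctamin-6	Ano6 Gt(AW0382)	C57Bl/6	07	o	nd	up	Prolonged bleeding
Anxa1	Annexin A1	PF4-Cre Anxa1	C57Bl/6	22	o	nd	nd	-
Apoe	Apolipoprotein E	Apoe tm1Unc	C57Bl/6	22	up	nd	nd	-
Bnip2	BCL2-interacting protein 2	Bnip2 tm1a	C57Bl/6N	21	o	nd	nd	-
Capn1	Calpain-1	Capn1 tm1Ahc	C57Bl/6	10	up	down	nd	Delayed vessel occlusion
Cd36	CD36	Cd36 tm1Mfe	C57Bl/6	14	o	down	o	Delayed thrombus formation, increased embolization
Cdc42	Small GTPase CDC42	PF4-Cre Cdc42	C57Bl/6 x 129SV	20	o	up	up	Accelerated vessel occlusion, prolonged bleeding
Clec1b	CLEC2	INU1 Ab	C57Bl/6	19	down	down	up	Delayed thrombus formation, increased embolization
Csk	Tyrosine kinase CSK	PF4-Cre Csk tm1Tara	C57Bl/6	23	down	down	up	Moderately reduced thrombus formation
Dlg4	Scaffold protein DLG4	Dlg4 tm1a	C57Bl/6N	21	o	nd	nd	-
Dusp3	Protein phosphatase DUSP3	Dusp3 tm1Srah	C57Bl/6	11	down	down	o	Decreased pulmonary embolism, small thrombus volume
Fcer1g	FcR gamma-chain	Fcer1g tm1Rav	C57Bl/6 x 129SV	04	down	down	nd	Delayed and reduced thrombus formation
Fpr2	Formyl peptide receptor-2	Fpr2 Tg(ACTB)#Jimw	C57Bl/6	22	up	nd	nd	-
Gnaq	Gq alpha-subunit	Gnaq tm1Soff	C57Bl/6 x 129SV	04	down	down	up	Intra-abdominal bleeding, frequent postnatal death, protection thromboembolism
Gp6	GPVI	Gp6 tm1Beni	C57Bl/6	03	down	down	o	Reduced thrombus stability, enhanced embolization
Gp6/Clec1b	GPVI/CLEC2	JAQ1+INU1 Ab	C57Bl/6	03	nd	down	up	Delayed thrombus formation, smaller thrombus volume
Grm8	Glutamate metabotropic receptor 8	Grm8 tm1a	C57Bl/6N	21	o	nd	nd	-
Ifnar1	Interferon receptor 1	Ifnar1 tm1a	C57Bl/6N	21	down	nd	nd	-
Itga2	Integrin alpha2	LoxP-Cre Itga2	C57Bl/6 x 129SV	05	down	down	o	Reduced thrombus formation, increased embolization
Itgb1	Integrin beta1	Mx-Cre Itgb1	C57Bl/6 x 129SV	04	down	o	o	Unchanged thrombus formation
Kcnn4	K-activated Ca channel-4	Kcnn4 tm1Rklr	C57Bl/6 x 129SV	16	o	nd	nd	-
Mpig6b	Receptor G6B-b	Mpig6b tm1.1Arte	C57Bl/6	24	down	nd	up	Prolonged bleeding
Orai1	Calcium channel ORAI1	BMC Orai1 -/-	C57Bl/6	01	down	down	o/up	Reduced thrombus formation and stability
Pik3cg	PI 3-kinase gamma	Pik3cg tm1Wym	129SV	13	down	down	o	Protected from thromboembolic vascular occlusion
Plcg2	Phospholipase C-gamma2 (GOF)	Plcg2 Ali5	C3HeB/FeJ	12	up	up	nd	Increased pulmonary thromboembolism
Pld1	Phospholipase D1	Pld1 tm3Mafr	C57Bl/6	02	o	down	o	Reduced thromboembolism, reduced thrombus stability
Prkca	Protein kinase C-alpha	Prkca Myh6/tetO/1Jmk	C57Bl/6	06	down	down	o	Delayed thrombus formation, no fecal occult blood
Prkcd	Protein kinase C-delta	Prkcd tm1Kin	C57Bl/6	06	up	o	nd	Unchanged thrombus formation
Prkcq	Protein kinase C-theta	Prkcq tm1Litt	C57Bl/6	06	up	nd	nd	Limited occlusion, thrombus instability
Prkd2	Protein kinase D2	Prkd2 tm1.1Daca	C57Bl/6	17	down	nd	o	Unchanged bleeding
Ptprj	Phosphatase CD148	PF4-Cre Ptprj tm1.1Weis	C57Bl/6	23	down	down	o	Severely compromised thrombus formation
Rac1	Small GTPase RAC1	Mx-Cre Rac1	C57Bl/6	08	down	down	up	Reduced thrombus formation and volume, variable but prolonged bleeding
Rhoa	Small GTPase RHO-A	PF4-Cre Rhoa	C57Bl/6 x 129SV	08	o	down	up	Unstable thrombus formation, increased embolization
Stim1	Regulator STIM1	BMC Stim1 -/-	C57Bl/6	01	down	down	up	Reduced thrombus stability, no vessel occlusion
Stim2	Regulator STIM2	Stim2 tm1Beni	C57Bl/6	01	o	nd	nd	-
Syk	Tyrosine kinase SYK	PF4-Cre Syk tm1(syk)Spwa	C57Bl/6	09	nd	down	up	Blood-filled lymphatics, impaired thrombus formation
Vps13a	Vacuolar sorting protein VPS13A	Vps13a tm1a	C57Bl/6N	21	down	nd	nd	-
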