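feature_id	vitamin	role	note
EC 2.5.1.3	B1	S	thiamine-phosphate synthase (ThiE)
EC 2.7.6.2	B1	S	thiamine diphosphokinase; produces TPP, the colonically absorbed form, so classified upstream
EC 2.2.1.1	B1	D	transketolase, TPP-dependent
EC 1.2.4.1	B1	D	pyruvate dehydrogenase E1, TPP-dependent
thiT	B1	T	thiamine transporter ThiT
EC 2.5.1.9	B2	S	riboflavin synthase (RibE)
EC 3.5.4.26	B2	S	diaminohydroxyphosphoribosylaminopyrimidine deaminase (RibD)
EC 2.7.1.26	B2	D	riboflavin kinase; converts riboflavin to FMN
EC 2.7.7.2	B2	D	FAD synthetase
ribU	B2	T	riboflavin transporter RibU
EC 1.4.3.16	B3	S	L-aspartate oxidase (NadB)
EC 2.5.1.72	B3	S	quinolinate synthase (NadA)
EC 6.3.4.21	B3	D	nicotinate phosphoribosyltransferase (PncB); consumes nicotinate
niaP	B3	T	niacin transporter NiaP
EC 6.3.2.1	B5	S	pantothenate synthetase (PanC)
EC 2.7.1.33	B5	S	pantothenate kinase; host enzymes dephosphorylate luminal phosphopantothenate, so classified upstream
EC 2.7.7.3	B5	D	phosphopantetheine adenylyltransferase, toward CoA
panT	B5	T	pantothenate transporter PanT
EC 4.3.3.6	B6	S	pyridoxal 5'-phosphate synthase (PdxS)
EC 2.7.1.35	B6	S	pyridoxal kinase; host enzymes dephosphorylate luminal PLP, so classified upstream
EC 4.1.1.15	B6	D	glutamate decarboxylase, PLP-dependent
EC 2.8.1.6	B7	S	biotin synthase (BioB)
EC 6.3.4.15	B7	D	biotin--protein ligase (BirA); attaches biotin to carboxylases
bioY	B7	T	biotin transporter BioY
EC 2.5.1.15	B9	S	dihydropteroate synthase (FolP)
EC 6.3.2.12	B9	S	dihydrofolate synthase (FolC)
EC 1.5.1.3	B9	D	dihydrofolate reductase; consumes folate
folT	B9	T	folate transporter FolT
EC 6.6.1.2	B12	S	cobaltochelatase (CobNST)
EC 2.5.1.17	B12	S	cob(I)alamin adenosyltransferase
EC 2.1.1.13	B12	D	methionine synthase (MetH), cobalamin-dependent
btuB	B12	T	cobalamin outer-membrane transporter BtuB
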