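# Disease-associated single amino-acid polymorphisms (SAPs) of human
# aquaporins, as reported in the UniProt/Swiss-Prot HUMSAVAR catalogue
# (release 2017_09), with structural location, hypothesized structural
# defect and prior-characterization flag (frick2014 = structural basis
# previously reported for AQP2 variants; aqp5study = structural basis
# previously reported for the AQP5/PPKB variants; functional-only =
# functional data only; none = no prior characterization).
protein	change	disease	location	defect	prior_structural_ref	variant_category
AQP2	p.Leu22Val	NDI	H1	tetramer assembly	none	Disease
AQP2	p.Leu28Pro	NDI	H1	monomer folding	none	Disease
AQP2	p.Ala47Val	NDI	H2	monomer folding	none	Disease
AQP2	p.Gln57Pro	NDI	H2	impaired metal binding	frick2014	Disease
AQP2	p.Gly64Arg	NDI	H2	pore features	none	Disease
AQP2	p.Asn68Ser	NDI	HB	pore features	frick2014	Disease
AQP2	p.Ala70Asp	NDI	HB	pore features	frick2014	Disease
AQP2	p.Val71Met	NDI	HB	pore features	frick2014	Disease
AQP2	p.Gly100Arg	NDI	H3	monomer folding	frick2014	Disease
AQP2	p.Gly100Val	NDI	H3	monomer folding	none	Disease
AQP2	p.Thr108Met	NDI	H3	monomer folding	none	Disease
AQP2	p.Thr125Met	NDI	loop C	tetramer assembly	frick2014	Disease
AQP2	p.Thr126Met	NDI	H4	tetramer assembly	frick2014	Disease
AQP2	p.Ala147Thr	NDI	H4	impaired metal binding	frick2014	Disease
AQP2	p.Val168Met	NDI	H5	pore features	frick2014	Disease
AQP2	p.Gly175Arg	NDI	H5	monomer folding	none	Disease
AQP2	p.Gly180Ser	NDI	H5	pore features	none	Disease
AQP2	p.Cys181Trp	NDI	loop E	monomer folding	none	Disease
AQP2	p.Pro185Ala	NDI	HE	pore features	frick2014	Disease
AQP2	p.Arg187Cys	NDI	HE	pore features	frick2014	Disease
AQP2	p.Arg187His	NDI	HE	pore features	frick2014	Disease
AQP2	p.Ala190Thr	NDI	HE	monomer folding	none	Disease
AQP2	p.Trp202Cys	NDI	H6	monomer folding	none	Disease
AQP2	p.Ser216Pro	NDI	H6	monomer folding	none	Disease
AQP2	p.Arg254Leu	NDI	C-ter	signal loss	functional-only	Disease
AQP2	p.Arg254Gln	NDI	C-ter	signal loss	functional-only	Disease
AQP2	p.Glu258Lys	NDI	C-ter	signal loss	functional-only	Disease
AQP2	p.Pro262Leu	NDI	C-ter	signal loss	functional-only	Disease
AQP5	p.Ala38Glu	PPKB	loop A	tetramer assembly	aqp5study	Disease
AQP5	p.Ile45Ser	PPKB	H2	pore features	aqp5study	Disease
AQP5	p.Asn123Asp	PPKB	loop C	tetramer assembly	aqp5study	Disease
AQP5	p.Ile177Phe	PPKB	H5	pore features	aqp5study	Disease
AQP5	p.Arg188Cys	PPKB	HE	pore features	aqp5study	Disease
AQP8	p.Ile229Met	colorectal tumor	H6	monomer folding	none	Unclassified
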