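go_id	go_term
GO:0000165	MAPKKK Cascade
GO:0002031	G-Protein Coupled Receptor Internalization
GO:0007194	Negative Regulation of Adenylate Cyclase Activity
GO:0007210	Serotonin Receptor Signaling Pathway
GO:0007212	Dopamine Receptor Signaling Pathway
GO:0007612	Learning
GO:0007613	Memory
GO:0008016	Regulation of Heart Contraction
GO:0009123	Nucleoside Monophosphate Metabolic Process
GO:0019935	Cyclic-Nucleotide-Mediated Signaling
GO:0043268	Positive Regulation of Potassium Ion Transport
GO:0043278	Response to Morphine
GO:0043408	Regulation of MAPKKK Cascade
GO:0045762	Positive Regulation of Adenylate Cyclase Activity
GO:0045823	Positive Regulation of Heart Contraction
GO:0045859	Regulation of Protein Kinase Activity
GO:0045893	Positive Regulation of Transcription, DNA-Dependent
GO:0046488	Phosphatidylinositol Metabolic Process
GO:0051924	Regulation of Calcium Ion Transport
GO:0051932	Synaptic Transmission, Gabaergic
GO:0051937	Catecholamine Transport
GO:0051969	Regulation of Transmission of Nerve Impulse
GO:0072511	Divalent Inorganic Cation Transport
GO:2000147	Positive Regulation of Cell Motility
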