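gene_symbol	drug_name	original_indication	score
IL6R	Sarilumab	Rheumatoid arthritis	4
IL6R	Satralizumab	Neuromyelitis optica spectrum disorder (NMOSD)	4
IL5	Reslizumab	Severe asthma	3
FTL	Sodium ferric gluconate complex	Iron deficiency anemia	2
FTL	Ferric pyrophosphate citrate	Iron deficiency	2
CD3D	Blinatumomab	Acute lymphoblastic leukemia (ALL)	2
ADORA1	Aminophylline	Asthma	2
ADORA1	Oxtriphylline	Asthma	2
CHRNA2	Metocurine iodide	Muscle contractions	2
CHRNA2	Doxacurium	General anesthesia	2
CHRNA2	Tubocurarine	General anesthesia	2
CHRNA2	Decamethonium	Muscle relaxant	2
CHRNA2	Metocurine	Muscle relaxant	2
CHRNA2	Pancuronium	Muscle relaxant	2
CHRNA2	Pipecuronium	Muscle relaxant	2
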