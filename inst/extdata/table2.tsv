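gene_symbol	drug_name	original_indication	source	identifier	printed_identifier
FTL	Iron Dextran	Iron deficiency	clinical	NCT03373253	3373253
IL5	Mepolizumab	Eosinophilic granulomatosis with polyangiitis (EGPA)	clinical	NCT04680611	4680611
IL6R	Tocilizumab	Rheumatoid arthritis	clinical	NCT03787290	3787290
ADORA1	Tramadol	Moderate to severe pain	clinical	NCT03309163	3309163
ADORA1	Caffeine	Migraine	clinical	NCT00025792	0025792
ADORA1	Theophylline	Chronic asthma	clinical	NCT01263106	1263106
ADORA1	Adenosine	Tachycardia	clinical	NCT02902601	2902601
ADORA1	Pentoxifylline	Intermittent claudication	clinical	NCT04417049	4417049
PRKCE	Tamoxifen	Breast cancer	clinical	NCT00667121	0667121
CHRNA2	Mecamylamine	Hypertension	clinical	NCT00593879	0593879
CHRNA2	Rocuronium	General anesthesia	clinical	NCT04565730	4565730
GABBR1	Taurine	Total parenteral nutrition	clinical	NCT00217165	0217165
CD3D	Muromonab	Prevention of organ rejection	preclinical	24257035	24257035
CD247	Muromonab	Prevention of organ rejection	preclinical	24257035	24257035
ADORA1	Dyphylline	Asthma	preclinical	10064181	10064181
CHRNA2	Carbamoylcholine	Open-angle glaucoma	preclinical	23603524	23603524
CHRNA2	Cisatracurium	General anesthesia	preclinical	22092267	22092267
CHRNA2	Atracurium besylate	General anesthesia	preclinical	8442962	8442962
CHRNA2	Mivacurium	General anesthesia	preclinical	8346843	8346843
CHRNA2	Vecuronium	Muscle relaxant	preclinical	8733812	8733812
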