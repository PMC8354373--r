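gene	classification	phenotype	inheritance
DDC	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
DNAJC12	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
GCH1	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AD and AR
PTS	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
QDPR	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
SLC18A2	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
SLC6A3	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
SPR	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
TH	Combined dystonia	Dopa-responsive dystonia-parkinsonism	AR
ADCY5	Combined dystonia	Dystonia-chorea-myoclonus	AD and AR
KMT2B	Combined dystonia	Generalized dystonia with prominent cranial involvement	AD
KCTD17	Combined dystonia	Myoclonus-dystonia	AD
SGCE	Combined dystonia	Myoclonus-dystonia	AD
TUBB4A	Combined dystonia	Generalized dystonia with prominent laryngeal dystonia	AD
PRKRA	Combined dystonia	Generalized dystonia-parkinsonism	AR
ATP1A3	Combined dystonia	Rapid-onset dystonia parkinsonism	AD
ANO3	Isolated dystonia	Adult-onset cranio-cervical dystonia	AD
GNAL	Isolated dystonia	Adult-onset cranio-cervical dystonia	AD and AR
HPCA	Isolated dystonia	Early-onset generalized dystonia	AR
THAP1	Isolated dystonia	Early-onset generalized dystonia	AD and AR
TOR1A	Isolated dystonia	Early-onset generalized dystonia	AD
SLC2A1	Paroxysmal dystonia	Paroxysmal exercise-induced dystonia	AD
KCNA1	Paroxysmal dystonia	Paroxysmal kinesigenic dystonia	AD
PRRT2	Paroxysmal dystonia	Paroxysmal kinesigenic dystonia	AD
SCN8A	Paroxysmal dystonia	Paroxysmal kinesigenic dystonia	AD
KCNMA1	Paroxysmal dystonia	Paroxysmal non-kinesigenic dystonia	AD
PNKD	Paroxysmal dystonia	Paroxysmal non-kinesigenic dystonia	AD
CACNA1A	Paroxysmal dystonia	Paroxysmal torticollis of infancy	AD
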