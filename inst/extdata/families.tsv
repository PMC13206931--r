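gene	family
Mef2c	Wnt
Gata4	Wnt
Pak1	MAPK
Camk2d	calcium
Igf1	IGF-1
Edn1	adrenergic
Nfatc3	calcium
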