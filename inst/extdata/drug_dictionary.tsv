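pattern	ingredient
SIMVASTATIN	simvastatin
ZOCOR	simvastatin
FLOLIPID	simvastatin
SIMVASTATINUM	simvastatin
ATORVASTATIN	atorvastatin
ATORVASTATIN CALCIUM	atorvastatin
LIPITOR	atorvastatin
SORTIS	atorvastatin
TORVAST	atorvastatin
ROSUVASTATIN	rosuvastatin
ROSUVASTATIN CALCIUM	rosuvastatin
CRESTOR	rosuvastatin
EZALLOR	rosuvastatin
PRAVASTATIN	pravastatin
PRAVASTATIN SODIUM	pravastatin
PRAVACHOL	pravastatin
SELEKTINE	pravastatin
FLUVASTATIN	fluvastatin
FLUVASTATIN SODIUM	fluvastatin
LESCOL	fluvastatin
LOVASTATIN	lovastatin
MEVACOR	lovastatin
ALTOPREV	lovastatin
PITAVASTATIN	pitavastatin
PITAVASTATIN CALCIUM	pitavastatin
LIVALO	pitavastatin
ZYPITAMAG	pitavastatin
CERIVASTATIN	cerivastatin
CERIVASTATIN SODIUM	cerivastatin
BAYCOL	cerivastatin
LIPOBAY	cerivastatin
COLCHICINE	colchicine
COLCRYS	colchicine
MITIGARE	colchicine
GLOPERBA	colchicine
LODOCO	colchicine
COLCHICINUM	colchicine
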