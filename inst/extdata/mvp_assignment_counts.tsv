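label	panel	coarse
European	459697	464961
Central/South Asian	709	NA
African	123687	123120
Admixed American	58034	52183
East Asian	10942	8329
Middle Eastern	763	NA
Unclassified	4750	9989
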