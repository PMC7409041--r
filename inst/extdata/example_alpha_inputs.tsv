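# viromics example alpha-diversity index pairs (published printed values): observed richness and Shannon index per site
site_id	observed	shannon
H0	2209	4.381
H3	1905	3.289
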