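# viromics example site metadata: two high-altitude wetland springs (published printed values)
site_id	conductivity	temperature	ph	oxygen	phosphate	vlp_per_ml	cells_per_ml	n_reads	total_bp
H0	566.3	19.3	8.87	14.56	0.081	2.5e6	2.1e5	11614382	2558493699
H3	580.7	17.6	8.68	8.32	0.090	1.3e6	5.3e5	10096566	2230955051
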