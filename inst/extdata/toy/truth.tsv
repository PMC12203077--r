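gene_id	de_type	direction	fold
gene00001	none	NA	1
gene00002	variance	down	1.5
gene00003	both	down	1.5
gene00004	mean	down	1.5
gene00005	none	NA	1
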