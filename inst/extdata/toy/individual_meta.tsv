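individual	group	z
ind001	0	-0.656535480040249
ind002	0	-1.36093960282672
ind003	0	-0.14198747768168
ind004	0	-0.80631455291145
ind005	1	-0.813615852222067
ind006	1	-1.02515383159349
ind007	1	-1.25889604883541
ind008	1	0.108566608475391
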