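ind001_c1
ind001_c2
ind001_c3
ind001_c4
ind001_c5
ind001_c6
ind001_c7
ind001_c8
ind001_c9
ind001_c10
ind001_c11
ind001_c12
ind002_c1
ind002_c2
ind002_c3
ind002_c4
ind002_c5
ind002_c6
ind002_c7
ind002_c8
ind002_c9
ind002_c10
ind002_c11
ind002_c12
ind003_c1
ind003_c2
ind003_c3
ind003_c4
ind003_c5
ind003_c6
ind003_c7
ind003_c8
ind003_c9
ind003_c10
ind003_c11
ind003_c12
ind004_c1
ind004_c2
ind004_c3
ind004_c4
ind004_c5
ind004_c6
ind004_c7
ind004_c8
ind004_c9
ind004_c10
ind004_c11
ind004_c12
ind005_c1
ind005_c2
ind005_c3
ind005_c4
ind005_c5
ind005_c6
ind005_c7
ind005_c8
ind005_c9
ind005_c10
ind005_c11
ind005_c12
ind006_c1
ind006_c2
ind006_c3
ind006_c4
ind006_c5
ind006_c6
ind006_c7
ind006_c8
ind006_c9
ind006_c10
ind006_c11
ind006_c12
ind007_c1
ind007_c2
ind007_c3
ind007_c4
ind007_c5
ind007_c6
ind007_c7
ind007_c8
ind007_c9
ind007_c10
ind007_c11
ind007_c12
ind008_c1
ind008_c2
ind008_c3
ind008_c4
ind008_c5
ind008_c6
ind008_c7
ind008_c8
ind008_c9
ind008_c10
ind008_c11
ind008_c12
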