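cell_id	individual
ind001_c1	ind001
ind001_c2	ind001
ind001_c3	ind001
ind001_c4	ind001
ind001_c5	ind001
ind001_c6	ind001
ind001_c7	ind001
ind001_c8	ind001
ind001_c9	ind001
ind001_c10	ind001
ind001_c11	ind001
ind001_c12	ind001
ind002_c1	ind002
ind002_c2	ind002
ind002_c3	ind002
ind002_c4	ind002
ind002_c5	ind002
ind002_c6	ind002
ind002_c7	ind002
ind002_c8	ind002
ind002_c9	ind002
ind002_c10	ind002
ind002_c11	ind002
ind002_c12	ind002
ind003_c1	ind003
ind003_c2	ind003
ind003_c3	ind003
ind003_c4	ind003
ind003_c5	ind003
ind003_c6	ind003
ind003_c7	ind003
ind003_c8	ind003
ind003_c9	ind003
ind003_c10	ind003
ind003_c11	ind003
ind003_c12	ind003
ind004_c1	ind004
ind004_c2	ind004
ind004_c3	ind004
ind004_c4	ind004
ind004_c5	ind004
ind004_c6	ind004
ind004_c7	ind004
ind004_c8	ind004
ind004_c9	ind004
ind004_c10	ind004
ind004_c11	ind004
ind004_c12	ind004
ind005_c1	ind005
ind005_c2	ind005
ind005_c3	ind005
ind005_c4	ind005
ind005_c5	ind005
ind005_c6	ind005
ind005_c7	ind005
ind005_c8	ind005
ind005_c9	ind005
ind005_c10	ind005
ind005_c11	ind005
ind005_c12	ind005
ind006_c1	ind006
ind006_c2	ind006
ind006_c3	ind006
ind006_c4	ind006
ind006_c5	ind006
ind006_c6	ind006
ind006_c7	ind006
ind006_c8	ind006
ind006_c9	ind006
ind006_c10	ind006
ind006_c11	ind006
ind006_c12	ind006
ind007_c1	ind007
ind007_c2	ind007
ind007_c3	ind007
ind007_c4	ind007
ind007_c5	ind007
ind007_c6	ind007
ind007_c7	ind007
ind007_c8	ind007
ind007_c9	ind007
ind007_c10	ind007
ind007_c11	ind007
ind007_c12	ind007
ind008_c1	ind008
ind008_c2	ind008
ind008_c3	ind008
ind008_c4	ind008
ind008_c5	ind008
ind008_c6	ind008
ind008_c7	ind008
ind008_c8	ind008
ind008_c9	ind008
ind008_c10	ind008
ind008_c11	ind008
ind008_c12	ind008
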