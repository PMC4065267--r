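s_name,label1,label2,incompatibility_group
S01,B10,B11,I
S02,A01,A03,II
S03,B06,,III
S04,B01,B13,IV
S05,A05,,V
S06,B04,C01,VI
S07,A01,A02,VII
S08,B03,,VIII
S09,A06,A07,
S10,B05,,
S11,B09,B12,
S12,B17,B18,
S13,A04,,
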