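cohort_id,collection,parent1,parent2,n,combination,count
c01,F1o,3,6,7,A01+A02+B10+B11,4
c01,F1o,3,6,7,A01+A03+B10+B11,3
c02,F1o,3,7,13,A01+A03+B10+B11,7
c02,F1o,3,7,13,B06+B10+B11,6
c03,F1o,8,4,5,A01+A03+A06+A07,2
c03,F1o,8,4,5,A06+A07+B10+B11,1
c03,F1o,8,4,5,A01+A03+B06,2
c04,F1o,8,6,7,A01+A03+A06+A07,1
c04,F1o,8,6,7,A01+A02+B06,3
c04,F1o,8,6,7,A01+A03+B06,3
c05,F1o,9,4,21,A01+A03,4
c05,F1o,9,4,21,B10+B11,1
c05,F1o,9,4,21,A01+A03+B06,10
c05,F1o,9,4,21,B06+B10+B11,6
c06,F1o,9,6,7,A01+A02,3
c06,F1o,9,6,7,A01+A03,2
c06,F1o,9,6,7,A01+A02+B06,2
c07,F1o,10,4,6,A01+A03+B01,1
c07,F1o,10,4,6,B01+B10+B11,4
c07,F1o,10,4,6,A01+A03+B06,1
c08,F1o,10,6,16,A01+A02+B01,2
c08,F1o,10,6,16,A01+A03+B01,6
c08,F1o,10,6,16,A01+A02+B06,6
c08,F1o,10,6,16,A01+A03+B06,2
c09,F1c,4,20,14,A01+A03+B03,3
c09,F1c,4,20,14,A01+A03+B05,2
c09,F1c,4,20,14,B03+B10+B11,4
c09,F1c,4,20,14,B05+B10+B11,5
c10,F1c,12,8,30,A05+A06+A07,7
c10,F1c,12,8,30,A05+B06,6
c10,F1c,12,8,30,A06+A07+B01,6
c10,F1c,12,8,30,B01+B06,11
c11,F1c,17,18,30,A01+A02+B04+C01,13
c11,F1c,17,18,30,B04+C01,17
c12,F1c,18,1,50,A01+A02+B09+B12,11
c12,F1c,18,1,50,A01+A02+B10+B11,15
c12,F1c,18,1,50,B04+B09+B12+C01,9
c12,F1c,18,1,50,B04+B10+B11+C01,15
c13,F1c,21,8,14,A04+A06+A07,5
c13,F1c,21,8,14,A04+B06,4
c13,F1c,21,8,14,A06+A07+B01,4
c13,F1c,21,8,14,B01+B06,1
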