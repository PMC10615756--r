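probeset,gene_symbol,direction
205278_at,GAD1,increased
215311_at,NTRK3,increased
209869_at,ADRA2A,increased
219764_at,FZD10,increased
210600_s_at,GRK4,increased
204311_at,ATP1B2,increased
242913_at,CLIC6,increased
1559360_at,EFNA5,increased
213170_at,GPX7,decreased
215025_at,NTRK3,increased
217214_s_at,SLC6A2,increased
242009_at,SLC6A4,increased
223113_at,TMEM138,decreased
229307_at,ANKRD28,increased
210381_s_at,CCKBR,increased
229106_at,DYNLL2,decreased
240253_at,Hs.550187,increased
208232_x_at,NRG1,increased
207332_s_at,TFRC,decreased
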