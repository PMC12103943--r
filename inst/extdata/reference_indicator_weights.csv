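indicator,criterion,weight
pop,pressure,0.1301
ndvi,state,0.1277
shdi,state,0.1184
shei,state,0.1257
cohesion,state,0.1251
esv,response,0.1229
contag,response,0.1275
frac_mn,response,0.1226
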