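simulated,paddy field,unirrigated field,forest land,grass land,water area,wet land,built-up land
paddy field,9601,98,256,47,80,18,353
unirrigated field,116,8511,39,25,32,11,254
forest land,296,28,7658,94,17,3,31
grass land,32,20,107,1779,5,0,12
water area,78,51,15,7,1430,23,13
wet land,12,2,2,1,35,194,2
built-up land,351,253,36,7,17,6,2910
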