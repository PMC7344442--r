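type,paddy field,unirrigated field,forest land,grass land,water area,wet land,built-up land
paddy field,1,1,1,1,1,1,1
unirrigated field,1,1,1,1,1,1,1
forest land,0,0,1,0,1,1,0
grass land,0,0,1,1,1,1,0
water area,0,0,0,0,1,0,0
wet land,0,0,0,0,1,1,0
built-up land,1,1,1,1,1,1,1
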