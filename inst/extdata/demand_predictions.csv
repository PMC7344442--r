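class,code,year,model,predicted_km2,actual_km2
paddy field,1,2015,gm11,41666.11,41483.58
unirrigated field,2,2015,gm11,35485.84,35446.85
forest land,3,2015,gm11,32074.64,32039.40
grass land,4,2015,gm11,8302.01,8283.79
water area,5,2015,gm11,6429.65,6513.68
wet land,6,2015,gm11,1028.66,983.80
built-up land,7,2015,gm11,15200.21,15383.28
paddy field,1,2018,gm11,41133.32,41108.65
unirrigated field,2,2018,gm11,35270.74,35095.26
forest land,3,2018,gm11,32021.62,32002.42
grass land,4,2018,gm11,8274.11,8285.71
water area,5,2018,gm11,6629.84,6683.98
wet land,6,2018,gm11,993.72,969.29
built-up land,7,2018,gm11,15984.16,15992.16
paddy field,1,2015,markov,42649.47,41483.58
unirrigated field,2,2015,markov,35898.24,35446.85
forest land,3,2015,markov,31886.70,32039.40
grass land,4,2015,markov,8342.97,8283.79
water area,5,2015,markov,6185.98,6513.68
wet land,6,2015,markov,1089.83,983.80
built-up land,7,2015,markov,13410.43,15383.28
paddy field,1,2018,markov,41068.75,41108.65
unirrigated field,2,2018,markov,35446.85,35095.26
forest land,3,2018,markov,31719.00,32002.42
grass land,4,2018,markov,8200.95,8285.71
water area,5,2018,markov,6513.68,6683.98
wet land,6,2018,markov,993.63,969.29
built-up land,7,2018,markov,15229.44,15992.16
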