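class,code,source,year,area_km2
paddy field,1,actual,2015,41483.58
unirrigated field,2,actual,2015,35446.85
forest land,3,actual,2015,32039.40
grass land,4,actual,2015,8283.79
water area,5,actual,2015,6513.68
wet land,6,actual,2015,983.80
built-up land,7,actual,2015,15383.28
paddy field,1,actual,2018,41108.65
unirrigated field,2,actual,2018,35095.26
forest land,3,actual,2018,32002.42
grass land,4,actual,2018,8285.71
water area,5,actual,2018,6683.98
wet land,6,actual,2018,969.29
built-up land,7,actual,2018,15992.16
paddy field,1,gm_forecast,2025,40251.45
unirrigated field,2,gm_forecast,2025,34691.73
forest land,3,gm_forecast,2025,31963.12
grass land,4,gm_forecast,2025,8260.34
water area,5,gm_forecast,2025,6782.26
wet land,6,gm_forecast,2025,954.93
built-up land,7,gm_forecast,2025,17997.14
paddy field,1,gm_forecast,2030,39555.06
unirrigated field,2,gm_forecast,2030,34268.22
forest land,3,gm_forecast,2030,31903.61
grass land,4,gm_forecast,2030,8238.71
water area,5,gm_forecast,2030,6932.36
wet land,6,gm_forecast,2030,927.83
built-up land,7,gm_forecast,2030,19667.92
paddy field,1,simulated,2025,40251.44
unirrigated field,2,simulated,2025,34691.72
forest land,3,simulated,2025,32545.68
grass land,4,simulated,2025,8260.36
water area,5,simulated,2025,6782.28
wet land,6,simulated,2025,954.92
built-up land,7,simulated,2025,16402.08
paddy field,1,simulated,2030,39555.08
unirrigated field,2,simulated,2030,34268.24
forest land,3,simulated,2030,32463.44
grass land,4,simulated,2030,8238.72
water area,5,simulated,2030,6932.36
wet land,6,simulated,2030,927.84
built-up land,7,simulated,2030,17502.80
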