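region,suitable_pct,marginal_pct,unsuitable_pct,suitable_km2e3,marginal_km2e3,unsuitable_km2e3
Gansu,4.20,4.31,91.49,19.06,19.55,415.09
Qinghai,1.93,1.82,96.25,13.86,13.07,691.34
Tibet,1.01,2.23,96.76,11.69,25.82,1120.17
Sichuan,8.02,7.85,84.13,38.71,37.89,406.12
Shaanxi,0.12,0.90,98.98,0.25,1.89,207.54
Other,NA,NA,NA,0.19,4.5,NA
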