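indicator,year,value,weight,tolerance,provenance
below_poverty_pct,2018,32.5,9.467456,0.325,printed trajectory value (exact print)
below_poverty_pct,2020,29.7,11.33779,0.297,printed trajectory value (exact print)
below_poverty_pct,2030,25,0.64,1.25,printed trajectory value (qualified: around)
below_poverty_pct,2050,16,1.5625,0.8,printed trajectory value (qualified: approximately)
food_insecurity_pct,2030,3,1111.111111,0.03,printed trajectory value (exact print)
gdp_growth_pct,2015,4.37,523.636756,0.0437,printed trajectory value (exact print)
gdp_growth_pct,2019,5.56,323.497226,0.0556,printed trajectory value (exact print)
gdp_growth_pct,2020,3.8,692.520776,0.038,printed trajectory value (exact print)
gdp_growth_pct,2030,11.99,69.560736,0.1199,printed trajectory value (exact print)
gdp_growth_pct,2050,13.71,53.209725,0.1371,printed trajectory value (exact print)
ghg_mt,2020,192,0.271267,1.92,printed trajectory value (exact print)
ghg_mt,2021,239,0.175067,2.39,printed trajectory value (exact print)
ghg_mt,2030,192,0.271267,1.92,printed trajectory value (exact print)
ghg_mt,2050,97,0.042508,4.85,printed trajectory value (qualified: around)
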