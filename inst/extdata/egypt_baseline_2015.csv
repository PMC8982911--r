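field,value,units,provenance
below_poverty_pct,27.8,%,table1
access_water_pct,98,%,table1
access_electricity_pct,100,%,table1
access_sanitation_pct,93,%,table1
gov_spend_essential_pct,5.59,%,table1
takafol_covered,2173274,person,table1
karama_covered,1239732,person,table1
undernourishment_pct,4.6,%,table1
food_price_anomaly_pct,10.99,%,table1
food_insecurity_pct,27.76,%,table1
production_per_labor,NA,USD,table1
child_malnutrition_pct,9.48,%,table1
inflation_pct,10.37,%,table1
gdp_pc_growth_pct,5.43,%,table1
tourism_share_pct,8.7,%,table1
unemployment_pct,13.05,%,table1
informal_employment_pct,30.94,%,table1
disaster_deaths,40,person,table1
ghg_mt,264.9,Mt CO2-eq,table1
drr_adaptation_level,0.2,dimensionless,table1
public_awareness_level,0.3,dimensionless,table1
below_poverty_pct,27.5,%,results_2015
ghg_mt,240,Mt CO2-eq,results_2015
gdp_growth_pct,4.37,%,results_2015
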