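product,cm3_per_dose,usd_per_dose,cold_chain
bcg_20dose,1.2,0.15,yes
penta_10dose,4.4,1.05,yes
measles_rubella_10dose,3.5,0.7,yes
opv_20dose,1.0,0.13,yes
ipv_5dose,9.7,1.9,yes
pcv13_4dose,12.0,3.3,yes
rotavirus_1dose,17.1,2.4,yes
td_10dose,3.0,0.1,yes
hpv_1dose,15.0,4.5,yes
ors_sachet,30.0,0.08,no
amoxicillin_dt_course,60.0,0.35,no
zinc_course,25.0,0.2,no
depo_provera_dose,40.0,0.85,no
implant_kit,120.0,8.5,no
male_condom_gross,4000.0,4.0,no
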