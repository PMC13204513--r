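model,me_mg_L,rel_me_pct,rel_mde_pct,rmse_mg_L,p30_pct,reported_n_met
Chung 2023,-0.46,12.2,4.2,8.00,49.3,5
Oudin 2011,-1.10,2.7,-11.7,8.37,50.0,4
Jung 2021,0.02,22.1,7.8,8.41,38.3,3
Germovsek 2019,-0.77,12.2,0.2,8.38,43.3,3
Marques-Minana 2010,0.31,25.7,12.9,8.78,35.5,3
De Hoog 2000,-1.25,9.4,-9.8,9.36,34.3,3
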