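year,stored_Mg,stored_value_MEUR,variation_MgC,co2_eq_Mg,variation_value_MEUR
2000,167359466.90,33471.89,NA,NA,NA
2006,166395908.00,33279.18,-963558.96,-3532052.52,-192.57
2012,164606707.10,32921.34,-1789200.82,-6558069.68,-357.57
2018,164813139.20,32962.63,206432.00,756919.47,41.26
2024,164202650.36,32840.53,-904289.49,-3315063.79,-180.72
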