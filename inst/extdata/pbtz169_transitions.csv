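analyte,istd,precursor_mz,product_mz,ion_ratio,quantifier,retention_time_min
PBTZ169,PBTZ169-d11,457.5,344.1,1,TRUE,3.0
PBTZ169,PBTZ169-d11,457.5,298.1,0.68,TRUE,3.0
Met 1-OH,11526102,473.3,344.1,1,TRUE,2.3
Met 1-OH,11526102,473.3,298.0,0.82,TRUE,2.3
Met 2-OH,11526102,473.5,344.1,1,TRUE,2.1
Met 2-OH,11526102,473.5,298.1,0.74,TRUE,2.1
Met 3-OH,11526102,473.4,344.1,1,TRUE,1.2
Met 3-OH,11526102,473.4,298.1,0.67,TRUE,1.2
Met 3-oxo,11526102,471.4,344.0,1,TRUE,1.5
Met 3-oxo,11526102,471.4,298.0,0.86,TRUE,1.5
Met oxo,11326128,471.3,361.1,1,TRUE,3.5
Met oxo,11326128,471.3,344.1,0.12,FALSE,3.5
Met oxo,11326128,471.3,318.0,0.08,FALSE,3.5
Met oxo,11326128,471.3,298.1,0.11,FALSE,3.5
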