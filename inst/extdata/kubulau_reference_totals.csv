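quantity,value,units
current_total_export,2142.7,t_yr
current_top3_export,1501.8,t_yr
deforestation_total_export,9583.8,t_yr
deforestation_additional_export,7441,t_yr
restoration_total_export,2118.5,t_yr
restoration_reduction,24.2,t_yr
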