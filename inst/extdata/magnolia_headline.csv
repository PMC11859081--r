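quantity,value
priority_area_1e4km2,54.73
protected_overlap_1e4km2,1.73
percent_unprotected_printed,96.84
m_insignis_total_1e4km2,205.04
china_land_area_1e4km2,960
m_insignis_land_fraction_printed,21.36
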