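year,planting_time,days_to_first_flower,anthesis_duration_d,yield_kg_ha
2011,early,42,70,773
2011,late,41,69,27
2012,early,54,55,327
2012,late,55,34,85
2013,early,44,57,430
2013,mid,36,54,387
2013,late,46,48,258
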