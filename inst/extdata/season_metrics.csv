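year,planting_time,coverage_time,pvt,flower_sum_billion
2011,early,1577,271,NA
2011,late,765,356,NA
2012,early,769,376,NA
2012,late,535,897,NA
2013,early,1113,1787,1.01
2013,mid,929,1774,4.59
2013,late,972,2662,0.96
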