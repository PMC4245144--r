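crop,gross_return_usd_ha,net_return_usd_ha
corn,2776,894
soybean,1628,526
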