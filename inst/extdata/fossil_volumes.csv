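specimen_id,alpha_vol_m3,n_points
Mammuthus primigenius,3.629,500000
Megatherium americanum,3.700,500000
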