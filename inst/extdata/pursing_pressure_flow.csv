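membrane_id,mwco_kda,exposed_diameter_mm,pressure_mmHg,flow_uL_min,source
visking_12_14kDa,13,20.0,150,0.66,"published pursing-rig reading: 12-14 kDa membrane, 20.0 mm exposed diameter at 150 mmHg"
visking_12_14kDa,13,15.0,150,0.54,"published pursing-rig reading: 12-14 kDa membrane, 15.0 mm exposed diameter at 150 mmHg"
visking_12_14kDa,13,5.0,150,0.05,"published pursing-rig reading: 12-14 kDa membrane, 5.0 mm exposed diameter at 150 mmHg"
visking_12_14kDa,13,20.0,361,2.0,"published pursing-rig reading: pressure drop at ~2.0 uL/min, 12-14 kDa membrane, 20.0 mm"
visking_50kDa,50,20.0,342,2.0,"published pursing-rig reading: pressure drop at ~2.0 uL/min, 50 kDa membrane, 20.0 mm"
visking_300kDa,300,20.0,7,2.0,"published pursing-rig reading: pressure drop at ~2.0 uL/min, 300 kDa membrane, 20.0 mm"
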