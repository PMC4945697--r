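# Cycle-mean per-lumen flows measured with 2D PC-MRI at three stations of
# the descending thoracic aorta (proximal, medial, distal). mm^3/s.
location,lumen,mean_flow_mm3_s
proximal,true,15100
medial,true,11100
distal,true,7900
proximal,false,40600
medial,false,42500
distal,false,42400
proximal,total,55600
medial,total,53800
distal,total,50300
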