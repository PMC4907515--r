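entry,pop_class,y_rf,y_ri
hs116,halfsib,595.7,564.9
hs26,halfsib,621,551.5
hs35,halfsib,593.9,584.3
hs39,halfsib,626,602.3
hs48,halfsib,616.5,648.8
hs65,halfsib,710.8,638.8
hs68,halfsib,623,628.3
hs79,halfsib,652.8,596.7
hs86,halfsib,709.3,566.4
hs91,halfsib,678.1,622
hsib,halfsib,650.9,597
HD2987,check,637.5,525
HD3043,check,695,462.5
HI1500,parent,335.7,726.1
HUW510,parent,182,651.6
base,base,353.6,673.2
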