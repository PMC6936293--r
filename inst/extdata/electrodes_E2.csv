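# Electrode configuration for the six-electrode machine wiring (experiment
# family E2): every electrode is an input during stimulation and an output
# during recording.  The published coordinate table parses to eight rows
# even though the wiring uses six electrodes; all eight parsed rows are
# shipped and a configuration selects which six labels form the machine
# (the package default takes the first six rows).
label,i,j,z,radius
e0,369,567,6,4
e1,509,580,10,4
e2,631,590,10,4
e3,382,322,12,4
e4,533,331,23,4
e5,369,424,7,4
e6,572,691,17,4
e7,705,394,17,4
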