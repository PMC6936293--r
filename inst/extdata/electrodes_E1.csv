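# Ten-electrode configuration (experiment family E1) on the 1024 x 1024 x 30
# laboratory network.  By convention e0 and e9 are the input electrodes and
# e1..e8 the outputs.  Radius in voxels; the recording/stimulation criterion
# is strictly d < radius.
label,i,j,z,radius
e0,369,567,6,4
e1,509,580,10,4
e2,631,590,10,4
e3,382,322,12,4
e4,533,331,23,4
e5,626,463,7,4
e6,358,676,22,4
e7,369,424,7,4
e8,572,691,17,4
e9,705,394,17,4
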