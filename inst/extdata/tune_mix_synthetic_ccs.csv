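label,mz,z,ccs_synthetic_a2
mz622,622,1,202.1
mz922,922,1,248.6
mz1222,1222,1,288.4
mz1522,1522,1,323.8
mz1822,1822,1,356.0
mz2122,2122,1,385.8
mz2422,2422,1,413.6
mz2722,2722,1,439.9
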