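species,host_class,hours,mean_pct,ci_lo,ci_hi,letter
ponderosa,historical,24,44.0,36.3,52.0,a
ponderosa,historical,48,67.3,59.4,74.4,a
ponderosa,historical,72,74.8,66.5,81.7,a
lodgepole,historical,24,28.0,19.9,36.9,b
lodgepole,historical,48,58.7,50.6,66.3,ab
lodgepole,historical,72,68.8,60.0,76.4,ab
jack,novel,24,31.3,23.0,40.7,b
jack,novel,48,50.7,42.7,58.6,b
jack,novel,72,56.7,47.7,65.3,bc
red,novel,24,38.7,29.5,48.4,ab
red,novel,48,60.0,52.0,67.5,ab
red,novel,72,68.1,59.3,75.8,ab
eastern_white,novel,24,17.3,11.2,24.9,c
eastern_white,novel,48,28.7,22.0,36.4,c
eastern_white,novel,72,47.3,38.5,56.3,c
scots,novel,24,30.0,19.7,42.1,b
scots,novel,48,57.8,47.4,67.5,ab
scots,novel,72,65.7,54.1,75.7,ab
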