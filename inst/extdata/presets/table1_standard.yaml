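# Standard-version GRIN miniaturized objective (cortex)
n0_axial: 1.643
pitch: 0.261
sqrt_a: 0.299
length_mm: 5.49
front_wd_mm: 0.15
n_front: 1.328
n_back: 1.000
na_mo: 0.483
angular_mag: 0.1675
label: standard version
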