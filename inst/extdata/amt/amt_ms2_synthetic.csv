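# synthetic reconstruction of the grey/red-powder product-ion scans:
# the fragment list (77, 91, 103, 158 from the 175 precursor) matches the
# reported diagnostic ions; collision-energy trends are emulated.
# label=grey powder MS2 CE10
# scan_type=MS2
# polarity=positive
# collision_energy=10
mz,intensity
77,30
91,70
103,90
158,450
175,800
176,78.4
# label=grey powder MS2 CE20
# scan_type=MS2
# polarity=positive
# collision_energy=20
mz,intensity
77,120
91,210
103,260
158,800
175,300
176,29.4
# label=grey powder MS2 CE30
# scan_type=MS2
# polarity=positive
# collision_energy=30
mz,intensity
77,250
91,360
103,330
158,420
175,60
# label=grey powder MS2 CE40
# scan_type=MS2
# polarity=positive
# collision_energy=40
mz,intensity
77,380
91,420
103,240
158,160
175,10
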