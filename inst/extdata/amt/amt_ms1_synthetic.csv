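# synthetic reconstruction of the grey/red-powder MS1 acquisition:
# the 175 cluster ratios (100 / 9.8 / 0.7) are the reported measurements;
# absolute scan-to-scan scaling emulates the in-source fragmentation
# profile with the [M+H]+ optimum at 70 eV and the 158 fragment
# dominating at 110 eV.
# label=grey powder MS1 F110
# scan_type=MS1
# polarity=positive
# fragmentor_voltage=110
mz,intensity
77,120
91,180
103,100
158,900
159,110
175,120
176,11.76
177,0.84
# label=grey powder MS1 F90
# scan_type=MS1
# polarity=positive
# fragmentor_voltage=90
mz,intensity
77,60
91,95
103,55
158,650
159,79
175,340
176,33.32
177,2.38
# label=grey powder MS1 F70
# scan_type=MS1
# polarity=positive
# fragmentor_voltage=70
mz,intensity
158,330
159,40
175,660
176,64.68
177,4.62
# label=grey powder MS1 F40
# scan_type=MS1
# polarity=positive
# fragmentor_voltage=40
mz,intensity
158,60
159,7.3
175,620
176,60.76
177,4.34
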