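# element_isotopes v1.0 -- stable isotope masses and natural abundances
# (CODATA/NIST standard values), unit-resolution MS support set
symbol,mass_number,exact_mass,abundance
H,1,1.0078250319,0.999885
H,2,2.0141017779,0.000115
C,12,12.0000000000,0.9893
C,13,13.0033548350,0.0107
N,14,14.0030740040,0.99636
N,15,15.0001088980,0.00364
O,16,15.9949146200,0.99757
O,17,16.9991317570,0.00038
O,18,17.9991596130,0.00205
F,19,18.9984031630,1.0
S,32,31.9720711740,0.9499
S,33,32.9714589100,0.0075
S,34,33.9678670110,0.0425
S,36,35.9670807100,0.0001
Cl,35,34.9688526820,0.7576
Cl,37,36.9659026020,0.2424
Br,79,78.9183376010,0.5069
Br,81,80.9162897150,0.4931
I,127,126.9044718530,1.0
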