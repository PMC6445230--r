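# neutral_losses v1.0 -- common small-molecule neutral losses at unit resolution
name,formula,diagnostic_of,radical
water,H2O,hydroxyl or carbonyl after reduction,FALSE
ammonia,NH3,primary amine,FALSE
methylamine,CH5N,N-methyl secondary amine,FALSE
carbon monoxide,CO,carbonyl or furan ring,FALSE
hydrogen cyanide,HCN,nitrile or N-heteroaromatic,FALSE
methyl radical,CH3,methyl substituent,TRUE
ethylene,C2H4,ethyl chain or retro-Diels-Alder,FALSE
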