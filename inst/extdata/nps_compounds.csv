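# nps_compounds v1.0 -- curated table of new psychoactive substances and
# common drugs of abuse for formula-level database correspondence.
# synonyms are |-separated. One neutral formula per nominal mass by design
# (isomers share a formula), so formula-level hits are unambiguous.
name,synonyms,formula,class
AMT,alpha-methyltryptamine|3-(2-aminopropyl)indole,C11H14N2,tryptamine
5-IT,5-(2-aminopropyl)indole,C11H14N2,tryptamine
DMT,N.N-dimethyltryptamine,C12H16N2,tryptamine
DET,N.N-diethyltryptamine,C14H20N2,tryptamine
5-MeO-DMT,5-methoxy-DMT,C13H18N2O,tryptamine
psilocin,4-HO-DMT,C12H16N2O,tryptamine
5-MAPB,1-(benzofuran-5-yl)-N-methylpropan-2-amine,C12H15NO,benzofuran
5-APB,1-(benzofuran-5-yl)propan-2-amine|nor-5-MAPB,C11H13NO,benzofuran
6-APB,1-(benzofuran-6-yl)propan-2-amine,C11H13NO,benzofuran
5-EAPB,1-(benzofuran-5-yl)-N-ethylpropan-2-amine,C13H17NO,benzofuran
2C-B,4-bromo-2.5-dimethoxyphenethylamine,C10H14BrNO2,phenethylamine
bk-2C-B,2-amino-1-(4-bromo-2.5-dimethoxyphenyl)ethan-1-one,C10H12BrNO3,phenethylamine
2C-I,4-iodo-2.5-dimethoxyphenethylamine,C10H14INO2,phenethylamine
25B-NBOMe,2C-B-NBOMe,C18H22BrNO3,phenethylamine
mescaline,3.4.5-trimethoxyphenethylamine,C11H17NO3,phenethylamine
amphetamine,alpha-methylphenethylamine,C9H13N,amphetamine
methamphetamine,N-methylamphetamine,C10H15N,amphetamine
MDA,3.4-methylenedioxyamphetamine,C10H13NO2,amphetamine
MDMA,3.4-methylenedioxy-N-methylamphetamine,C11H15NO2,amphetamine
MDEA,3.4-methylenedioxy-N-ethylamphetamine,C12H17NO2,amphetamine
PMA,para-methoxyamphetamine,C9H13NO,amphetamine
PMMA,para-methoxy-N-methylamphetamine,C10H15NO,amphetamine
4-FA,4-fluoroamphetamine,C9H12FN,amphetamine
methcathinone,ephedrone,C10H13NO,cathinone
mephedrone,4-methylmethcathinone|4-MMC,C11H15NO,cathinone
4-MEC,4-methylethcathinone,C12H17NO,cathinone
pentedrone,alpha-methylaminovalerophenone,C12H17NO,cathinone
butylone,bk-MBDB,C12H15NO3,cathinone
MDPV,methylenedioxypyrovalerone,C16H21NO3,cathinone
alpha-PVP,alpha-pyrrolidinopentiophenone|flakka,C15H21NO,cathinone
naphyrone,naphthylpyrovalerone,C19H23NO,cathinone
BZP,benzylpiperazine,C11H16N2,piperazine
mCPP,meta-chlorophenylpiperazine,C10H13ClN2,piperazine
ketamine,2-(2-chlorophenyl)-2-(methylamino)cyclohexan-1-one,C13H16ClNO,arylcyclohexylamine
methoxetamine,MXE,C15H21NO2,arylcyclohexylamine
cocaine,benzoylmethylecgonine,C17H21NO4,tropane alkaloid
morphine,,C17H19NO3,opioid
codeine,3-methylmorphine,C18H21NO3,opioid
fentanyl,,C22H28N2O,opioid
THC,delta-9-tetrahydrocannabinol,C21H30O2,cannabinoid
JWH-018,naphthalen-1-yl(1-pentylindol-3-yl)methanone,C24H23NO,synthetic cannabinoid
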