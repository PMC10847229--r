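unilateral,bilateral
AI_L,AI
AI_R,AI
AuDMV_L,AuDMV
AuDMV_R,AuDMV
CC_L,CC
CC_R,CC
Cg_L,Cg
Cg_R,Cg
CPu_L,CPu
CPu_R,CPu
DI_L,DI
DI_R,DI
DLIVEnt_L,DLIVEnt
DLIVEnt_R,DLIVEnt
DLO_L,DLO
DLO_R,DLO
ECT_L,ECT
ECT_R,ECT
Fornix_L,Fornix
Fornix_R,Fornix
FrA_L,FrA
FrA_R,FrA
HIP_L,HIP
HIP_R,HIP
LO_L,LO
LO_R,LO
M1_L,M1
M1_R,M1
M2_L,M2
M2_R,M2
MO_L,MO
MO_R,MO
PRH_L,PRH
PRH_R,PRH
PrL_L,PrL
PrL_R,PrL
PtA_L,PtA
PtA_R,PtA
PtPR_L,PtPR
PtPR_R,PtPR
RSC_L,RSC
RSC_R,RSC
S1_L,S1
S1_R,S1
S2_L,S2
S2_R,S2
TeA_L,TeA
TeA_R,TeA
TH_L,TH
TH_R,TH
V1V2_L,V1V2
V1V2_R,V1V2
VO_L,VO
VO_R,VO
Cerebellum_L,Cerebellum
Cerebellum_R,Cerebellum
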