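# microarray duplex free-energy parameter set (kcal/mol)
[global]
m_value =       0.173
effective_probe_conc = 0.009948626824
dg_init =        1.96
gas_constant =     0.00199
temperature =      315.15
bulge_alpha =       0.238
sm_linear_alpha =       0.354
sm_linear_beta =       0.487
tandem_linear_alpha =       0.198
tandem_linear_beta =       1.167

[nearest_neighbors]
AA =        -0.3
AC =      -0.432
AG =      -0.384
AT =      -0.264
CA =      -0.435
CC =      -0.552
CG =      -0.651
GA =       -0.39
GC =      -0.672
TA =      -0.174

[single_mismatch_loops]
AAA/TAT =      0.6003
AAA/TCT =      0.5988
AAA/TGT =      0.3258
AAC/TAG =      0.3035
AAC/TCG =       0.542
AAC/TGG =       0.029
AAG/TAC =      0.4256
AAG/TCC =      0.6641
AAG/TGC =       0.151
AAT/TAA =      0.5199
AAT/TCA =      0.7584
AAT/TGA =      0.2454
ACA/TAT =      0.7798
ACA/TCT =      0.7783
ACA/TTT =      0.4604
ACC/TAG =       0.483
ACC/TCG =      0.7215
ACC/TTG =      0.4036
ACG/TAC =      0.6051
ACG/TCC =      0.6035
ACG/TTC =      0.2857
ACT/TCA =      0.9379
ACT/TTA =        0.38
AGA/TAT =      0.1488
AGA/TGT =     -0.1258
AGA/TTT =      0.1194
AGC/TAG =       0.092
AGC/TGG =     -0.1825
AGC/TTG =      0.0626
AGG/TAC =      0.2141
AGG/TGC =     -0.3005
AGG/TTC =     -0.0554
AGT/TGA =      0.0338
AGT/TTA =       0.039
ATA/TCT =       0.439
ATA/TGT =       0.216
ATA/TTT =      0.5711
ATC/TCG =      0.3822
ATC/TGG =     -0.0808
ATC/TTG =      0.5143
ATG/TCC =      0.2643
ATG/TGC =      0.0412
ATG/TTC =      0.3964
ATT/TTA =      0.4907
CAA/GAT =      0.4658
CAA/GCT =      0.4643
CAA/GGT =      0.1912
CAC/GAG =       0.169
CAC/GCG =      0.4075
CAC/GGG =     -0.1055
CAG/GAC =       0.291
CAG/GCC =      0.2895
CAG/GGC =      0.0165
CCA/GAT =      0.6453
CCA/GCT =      0.6437
CCA/GTT =      0.3259
CCC/GAG =      0.3485
CCC/GCG =       0.587
CCC/GTG =      0.2691
CCG/GCC =       0.469
CCG/GTC =      0.1511
CGA/GAT =      0.0143
CGA/GGT =     -0.2603
CGA/GTT =     -0.0152
CGC/GAG =     -0.0425
CGC/GGG =     -0.3171
CGC/GTG =     -0.3119
CGG/GGC =      -0.435
CGG/GTC =     -0.1899
CTA/GCT =      0.3044
CTA/GGT =     -0.1586
CTA/GTT =      0.4366
CTC/GCG =      0.2477
CTC/GGG =     -0.2153
CTC/GTG =      0.3798
CTG/GTC =      0.2618
GAA/CAT =      0.3478
GAA/CCT =      0.5863
GAA/CGT =      0.0732
GAC/CAG =       0.291
GAC/CCG =      0.2895
GAC/CGG =      0.0165
GCA/CAT =      0.5273
GCA/CCT =      0.7658
GCA/CTT =      0.4479
GCC/CCG =       0.469
GCC/CTG =      0.1511
GGA/CAT =      0.1363
GGA/CGT =     -0.1383
GGA/CTT =     -0.1331
GGC/CGG =      -0.435
GGC/CTG =     -0.1899
GTA/CCT =      0.4265
GTA/CGT =     -0.0366
GTA/CTT =      0.5586
GTC/CTG =      0.2618
TAA/AAT =      0.5199
TAA/ACT =      0.7584
TAA/AGT =      0.2454
TCA/ACT =      0.9379
TCA/ATT =        0.38
TGA/AGT =      0.0338
TGA/ATT =       0.039
TTA/ATT =      0.4907

[bulge_solution_loops]
AAA =      3.3893
AAC =      2.6999
AAG =      2.9211
AAT =        3.24
ACA =       3.063
ACC =      2.9736
ACG =      3.1948
ACT =      3.5138
AGA =      3.0105
AGC =      2.9211
AGG =      3.1423
AGT =      2.8612
ATA =      3.0898
ATC =      3.0004
ATG =      3.2216
ATT =      3.5405
CAA =      2.6999
CAC =      2.5368
CAG =       2.758
CAT =      3.0769
CCA =      2.9736
CCC =      2.8105
CCG =      3.0317
CCT =      3.3506
CGA =      2.9211
CGC =       2.758
CGG =      2.9792
CGT =      2.6981
CTA =      3.0004
CTC =      2.8373
CTG =      3.0585
CTT =      3.3774
GAA =      2.9211
GAC =       2.758
GAG =      2.8317
GAT =      3.1506
GCA =      3.1948
GCC =      3.0317
GCG =      3.1055
GCT =      2.8244
GGA =      3.1423
GGC =      2.9792
GGG =      2.4529
GGT =      2.7719
GTA =      3.2216
GTC =      3.0585
GTG =      3.1322
GTT =      2.8511
TAA =        3.24
TAC =      3.0769
TAG =      3.1506
TAT =      2.9903
TCA =      3.5138
TCC =      3.3506
TCG =      2.8244
TCT =       3.264
TGA =      2.8612
TGC =      2.6981
TGG =      2.7719
TGT =      3.2115
TTA =      3.5405
TTC =      3.3774
TTG =      2.8511
TTT =      3.2908

[tandem_scores]
AT:GG =        0.35
GC:GG =        0.05
AT:GA =        0.45
GC:GA =        0.15
AT:GT =         0.4
GC:GT =         0.1
AT:other =         0.9
GC:other =         0.6
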