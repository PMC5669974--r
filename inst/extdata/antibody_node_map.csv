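antibody,node,excluded,note
BAD (S155),BAD,FALSE,phosphosite S155
c-Kit (Y703),cKIT,FALSE,phosphosite Y703
AMPKBbeta1 (S108),AMPK,FALSE,AMPK beta1 subunit S108
cKit (Y719),cKIT,FALSE,phosphosite Y719
ErbB4/HER4 (111B2),ERBB4,FALSE,clone 111B2
Caspase-9 cleaved (D330),CASP,FALSE,cleaved caspase readout
Caspase-3. cleaved (D175),CASP,FALSE,cleaved caspase readout
LKB1 (S428),LKB1,FALSE,phosphosite S428
EGFR (Y1148),EGFR,FALSE,phosphosite Y1148
MEK1/2 (S217/221),MEK,FALSE,activation loop sites
BAD (S136),BAD,FALSE,phosphosite S136
Src family (Y416),,TRUE,Src not a model node
c-Raf (S338),,TRUE,RAF1 isoform distinct from model RAF node
PRAS40 (T246),,TRUE,not a model node
4E-BP1 (T70),,TRUE,not a model node
IGF-1 Rec (Y1135/36)/Insulin Rec (Y1150/51),IGF1R,FALSE,activation loop sites
Elk-1 (S383),,TRUE,not a model node
EGFR (Y992),EGFR,FALSE,phosphosite Y992
Caspase-7. cleaved (D198),CASP,FALSE,cleaved caspase readout
c-Kit (CD117),,TRUE,total protein antibody
Survivin (71G4),,TRUE,not a model node
p70S6 Kinase (T412),,TRUE,site outside the S371/T389 activation set
eIF2alpha (S51),,TRUE,not a model node
Cyclin D1 (G124-326),,TRUE,not a model node
IRS-1 (S612),,TRUE,not a model node
Bcl-2 (S70),,TRUE,not a model node
p38 MAP kinase (T180/Y182),,TRUE,not a model node
EGFR (Y1173),EGFR,FALSE,phosphosite Y1173
Histone Deacetylase 3 (HDAC3),,TRUE,not a model node
SAPK/JNK (T183/Y185),,TRUE,not a model node
a-Raf (S299),,TRUE,ARAF isoform distinct from model RAF node
mTOR (S2448),mTOR,FALSE,phosphosite S2448
GSK-3alpha/beta (S21/9),,TRUE,not a model node
TNF-R1 (C25C1),,TRUE,not a model node
4E-BP1 (S65),,TRUE,not a model node
p70S6 Kinase (T389),p70S6K,FALSE,phosphosite T389
Cyclin A (BF683),,TRUE,not a model node
Caspase-6 cleaved (D162),CASP,FALSE,cleaved caspase readout
Bax,,TRUE,not a model node
Stat3 (S727),,TRUE,isolated protein excluded from model
EGFR,,TRUE,total protein antibody
ERK 1/2 (T202/Y204),ERK,FALSE,activation loop sites
p70S6 Kinase (S371),p70S6K,FALSE,phosphosite S371
Tubulin. alpha acetylated (6-11B-1),,TRUE,isolated protein excluded from model
b-Raf (S445),RAF,FALSE,BRAF S445
Bak,,TRUE,isolated protein excluded from model
NQO1,,TRUE,isolated protein excluded from model
Cox-2,,TRUE,isolated protein excluded from model
Heme Oxygenase 1,,TRUE,isolated protein excluded from model
Smad2 (S245/250/255),,TRUE,isolated protein excluded from model
Src (Y527),,TRUE,Src not a model node
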