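uniprot	gene	entrez
1433B	Ywhab	54401
1433E	Ywhae	22627
1433G	Ywhag	22628
1433Z	Ywhaz	22631
AATM	Got2	14719
ACTB	Actb	11461
ACTC	Actc1	11464
ACTN1	Actn1	109711
ACTN2	Actn2	11472
ADT1	Slc25a4	11739
ADT2	Slc25a5	11740
AGK	Agk	69923
AINX	Ina	226180
ALDOA	Aldoa	11674
ANS1B	Anks1b	77531
AT1A1	Atp1a1	11928
AT1A3	Atp1a3	232975
AT1B1	Atp1b1	11931
ATPA	Atp5a1	11946
ATPB	Atp5b	11947
BAIP2	Baiap2	108100
BASP1	Basp1	70350
BSN	Bsn	12217
C1QBP	C1qbp	12261
CA2D1	Cacna2d1	12293
CA2D2	Cacna2d2	56808
CA2D3	Cacna2d3	12294
CAD13	Cdh13	12554
CALM	Calm1	12313
CLCB	Cltb	74325
CLCN6	Clcn6	26372
CLD11	Cldn11	18417
CLH1	Cltc	67300
CMC1	Slc25a12	78830
CN37	Cnp	12799
CNTN1	Cntn1	12805
CNTN2	Cntn2	21367
CNTP1	Cntnap1	53321
COX2	Mtco2	17709
COX5A	Cox5a	12858
CSPG2	Vcan	13003
CTNA2	Ctnna2	12386
DLG4	Dlg4	13385
DLGP3	Dlgap3	242667
DPYL2	Dpysl2	12934
DYL1	Dynll1	56455
ENPP6	Enpp6	320981
ERC2	Erc2	238988
FLOT1	Flot1	14251
FLOT2	Flot2	14252
G3P	Gapdh	14433
GBB1	Gnb1	14688
GBG12	Gng12	14701
GBG2	Gng2	14702
GNAI1	Gnai1	14677
GNAI2	Gnai2	14678
GNAO	Gnao1	14681
GNAS1	Gnas	14683
GNAZ	Gnaz	14687
HOME1	Homer1	26556
HPLN1	Hapln1	12950
HPLN2	Hapln2	73940
HS71L	Hspa1l	15482
HSP7C	Hspa8	15481
HXK1	Hk1	15275
IGS21	Igsf21	230868
IQEC1	Iqsec1	232227
IQEC2	Iqsec2	245666
KCC2A	Camk2a	12322
KCC2B	Camk2b	12323
KCC2D	Camk2d	108058
KCC2G	Camk2g	12325
KCRB	Ckb	12709
LSAMP	Lsamp	268890
LY6H	Ly6h	23934
MAP1A	Map1a	17754
MBP	Mbp	17196
MDHM	Mdh2	17448
ML12B	Myl12b	67938
MOBP	Mobp	17433
MOG	Mog	17441
MYH10	Myh10	77579
MYH9	Myh9	17886
MYL6	Myl6	17904
MYO5A	Myo5a	17918
MYPR	Plp1	18823
NCAM1	Ncam1	17967
NCAN	Ncan	13004
NDUA4	Ndufa4	17992
NEGR1	Negr1	320840
NEUM	Gap43	14432
NFL	Nefl	18039
NFM	Nefm	18040
NTRI	Ntm	235106
ODO2	Dlst	78920
ODP2	Dlat	235339
OMGP	Omg	18377
PCLO	Pclo	26875
PRIO	Prnp	19122
RAC1	Rac1	19353
SCAI	Scai	320271
SEPT7	Sept7	235072
SHAN3	Shank3	58234
SNP25	Snap25	20614
SPTA2	Sptan1	20740
SPTB2	Sptbn1	20742
STX1B	Stx1b	56216
SYGP1	Syngap1	240057
SYPH	Syp	20977
SYT1	Syt1	20979
SYT2	Syt2	20980
TBA1A	Tuba1a	22142
TBA1B	Tuba1b	22143
TBA3	Tuba3a	22144
TBA4A	Tuba4a	22145
TBB2A	Tubb2a	22151
TBB3	Tubb3	22152
TBB4A	Tubb4a	22153
TBB4B	Tubb4b	227613
TBB5	Tubb5	22154
THY1	Thy1	21838
TPM3	Tpm3	59069
VA0D1	Atp6v0d1	11972
VAMP2	Vamp2	22318
VATA	Atp6v1a	11964
VATB2	Atp6v1b2	11966
VATC1	Atp6v1c1	66335
VATD	Atp6v1d	73834
VATE1	Atp6v1e1	11973
VATF	Atp6v1f	66144
VATG2	Atp6v1g2	66237
VDAC1	Vdac1	22333
VPP1	Atp6v0a1	11975
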