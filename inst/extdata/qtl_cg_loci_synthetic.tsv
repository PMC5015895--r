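gene	chrom	start	end
KCNIP4	6	2080183	2428534
CCSER1	6	3218229	3455597
DPP6	4	4259198	4311892
MAP3K5	9	5046417	5160763
GHR	20	5337535	5781810
CAST	7	5878881	6173674
GH1	6	6057628	6927856
IGF1	1	12378119	12834449
IGF1R	11	13006159	13880518
IGF2	12	13125219	13909626
IGFBP1	14	13600949	14081200
IGFBP2	18	18704140	19185172
IGFBP3	2	18806432	19147649
IGFBP5	14	19129412	20013254
MSTN	12	19477872	20292027
LEP	13	20537980	21301709
LEPR	17	23980546	24084794
MYF5	13	24055919	24784107
MYF6	20	25716410	26315867
MYOD1	12	28982710	29162047
MYOG	18	29765046	30027482
POMC	18	30657673	31123621
NPY	19	30687434	31312154
MC4R	12	33462389	33659728
CAPN1	16	35035050	35863770
CAPN3	2	36429735	37295213
PRKAG3	25	38760598	39413514
DGAT1	9	39695160	40022161
SCD	8	39971878	40107087
FASN	26	41906995	42799288
SREBF1	9	43294656	44098199
PPARG	6	43295512	44119963
PPARGC1A	18	47056922	47745262
ADIPOQ	2	48483032	48689980
FABP4	18	49961758	50423432
CRH	4	51908455	51962016
CRHR1	27	54198600	55049868
TRH	21	54751592	55201630
TSHB	20	56528458	57222250
TSHR	6	57163971	57965449
PRL	15	58134805	59007876
PRLR	16	59474049	59511547
STAT5A	6	64425322	64841224
STAT5B	20	66400968	67058204
JAK2	25	68947482	69787468
SOCS2	22	69299160	69344033
FGF2	16	72359807	72419436
FGFR1	12	72442996	72554986
EGF	2	74694651	74994326
EGFR	3	74853099	74875101
TGFB1	7	75586442	76005511
BMP2	9	76534374	76639834
BMP4	11	76654525	76812353
GDF8R	2	76686163	77403742
INHA	23	78065066	78163316
INHBA	27	80342972	81015793
FSHB	9	80704695	81441563
FSHR	13	82186956	82648262
LHB	14	82988084	83233692
LHCGR	25	83661040	83774333
GNRH1	19	83818724	84239797
GNRHR	25	87817369	88145435
KISS1	12	88338125	88896676
KISS1R	21	88667505	89462786
ESR1	1	88817577	89652601
AR	28	90100995	90216933
THRA	10	91262713	91518710
THRB	11	91532863	91769508
DIO1	25	91908311	92611196
DIO2	21	92171130	92636007
SST	15	98928569	99525752
SSTR2	29	101187355	101362857
GHSR	2	102484287	102795961
GHRL	1	104839279	105666891
PIT1	29	106397093	106592999
PROP1	24	107997215	108698531
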