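feature	start	end
D-loop	16024	576
TRNF	577	647
RNR1	648	1601
TRNV	1602	1670
RNR2	1671	3229
TRNL1	3230	3304
ND1	3307	4262
TRNI	4263	4331
TRNQ	4329	4400
TRNM	4402	4469
ND2	4470	5511
TRNW	5512	5579
TRNA	5587	5655
TRNN	5657	5729
TRNC	5761	5826
TRNY	5826	5891
CO1	5904	7445
TRNS1	7446	7514
TRND	7518	7585
CO2	7586	8269
TRNK	8295	8364
ATP8	8366	8572
ATP6	8527	9207
CO3	9207	9990
TRNG	9991	10058
ND3	10059	10404
TRNR	10405	10469
ND4L	10470	10766
ND4	10760	12137
TRNH	12138	12206
TRNS2	12207	12265
TRNL2	12266	12336
ND5	12337	14148
ND6	14149	14673
TRNE	14674	14742
CYTB	14747	15887
TRNT	15888	15953
TRNP	15956	16023
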