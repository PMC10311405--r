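kmer	level_mean
AAA	84.089689
AAC	90.265944
AAG	74.834469
AAT	76.373467
ACA	101.784892
ACC	80.658487
ACG	103.236056
ACT	96.249178
AGA	89.542770
AGC	79.958794
AGG	81.715668
AGT	86.516483
ATA	74.617066
ATC	87.444348
ATG	78.500550
ATT	90.123270
CAA	87.770305
CAC	98.877716
CAG	84.078447
CAT	83.442819
CCA	83.174824
CCC	89.841418
CCG	85.573952
CCT	93.525575
CGA	90.731706
CGC	90.071588
CGG	88.123999
CGT	82.342994
CTA	87.789432
CTC	80.164114
CTG	78.957160
CTT	80.618498
GAA	96.786242
GAC	74.225021
GAG	81.300615
GAT	94.846770
GCA	88.139473
GCC	105.455547
GCG	83.886199
GCT	86.522435
GGA	73.634837
GGC	90.203814
GGG	98.917427
GGT	81.272503
GTA	98.900508
GTC	86.561257
GTG	68.132186
GTT	98.800582
TAA	97.238566
TAC	92.198527
TAG	97.898706
TAT	87.700061
TCA	81.814975
TCC	94.997342
TCG	91.591923
TCT	95.426264
TGA	88.433549
TGC	94.387933
TGG	104.878706
TGT	90.601651
TTA	81.509871
TTC	113.396931
TTG	88.787970
TTT	70.497926
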