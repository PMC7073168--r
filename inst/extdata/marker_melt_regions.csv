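marker_id,primer_pair,premelt_lo,premelt_hi,postmelt_lo,postmelt_hi,lower_limit,upper_limit
SNP_IGA_122351,S1_4102b-f1/r1,72.6,73.0,82.0,82.5,73.0,82.0
SNP_IGA_297497,S3_0363-f2/r2,69.1,69.5,79.8,80.2,63.5,79.0
SNP_IGA_769251,S7_1256-f1/r1,78.7,79.1,87.0,87.5,79.1,87.0
SNP_IGA_779222,S7_1611-f1/r1,72.7,73.1,81.8,82.3,77.5,82.0
rs159238319,S1_1690-f2/r2,67.1,67.5,77.1,77.6,67.5,77.0
SNP_IGA_134905,S1_4631-f2/r2,74.5,74.9,82.6,83.1,73.0,82.5
SNP_IGA_381567,S4_2429-f2/r2,68.7,69.1,78.1,78.6,69.0,78.0
SNP_IGA_419106,S4_1351-f1/r2,69.6,70.1,76.3,76.8,70.1,76.3
SNP_IGA_695463,S6_2645-f2/r2,73.6,74.0,83.2,83.7,74.0,83.5
SNP_IGA_786935,S7_1954b-f1/r1,77.2,77.6,83.9,84.4,77.6,83.9
SNP_IGA_112592,S1_3674-f2/r2,68.6,69.0,77.8,78.2,69.0,78.5
rs159239801,S4_9208b-f1/r1,71.0,71.5,77.2,77.7,71.5,77.7
SNP_IGA_780662,S7_1667-f1/r1,75.7,76.0,85.2,85.6,77.5,85.0
SNP_IGA_131284,S1_4475-f1/r1,71.4,71.8,79.5,80.0,71.8,79.5
1_40995799,S1_4099-f1/r1,74.2,74.4,82.1,82.5,74.0,82.5
2_16900230,S2_1690-f1/r1,79.1,79.3,85.5,86.2,79.3,85.5
4_00772820,S4_0077-f1/r1,72.1,72.3,80.2,80.6,72.5,80.0
4_11060745,S4_1106-f1/r1,77.9,78.1,85.4,85.8,77.0,85.5
4_13747914,S4_1374-f1/r1,74.8,75.0,81.1,81.3,75.0,81.0
SNP_IGA_427604,S4_1498b-f2/r2,72.9,73.3,80.5,81.0,73.0,81.0
5_13713689,S5_1371-f2/r2,74.7,75.2,82.5,83.0,75.0,82.5
8_11718744,S8_1171-f1/r1,74.2,74.6,80.9,81.5,70.5,80.5
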