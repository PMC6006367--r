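# synthetic road network: irregularly thinned 8x8 lattice, 64 nodes
x1_1 x1_2
x1_1 x2_1
x1_2 x1_3
x1_2 x2_2
x1_4 x1_5
x1_4 x2_4
x1_5 x1_6
x1_5 x2_5
x1_6 x1_7
x1_6 x2_6
x1_7 x1_8
x2_1 x2_2
x2_1 x3_1
x2_3 x2_4
x2_3 x3_3
x2_4 x2_5
x2_5 x2_6
x2_5 x3_5
x2_7 x3_7
x2_8 x3_8
x3_1 x3_2
x3_2 x3_3
x3_2 x4_2
x3_3 x4_3
x3_4 x3_5
x3_5 x3_6
x3_5 x4_5
x3_6 x3_7
x3_6 x4_6
x3_7 x3_8
x4_1 x5_1
x4_2 x4_3
x4_2 x5_2
x4_3 x4_4
x4_3 x5_3
x4_4 x4_5
x4_4 x5_4
x4_5 x5_5
x4_6 x4_7
x4_6 x5_6
x4_7 x4_8
x4_7 x5_7
x4_8 x5_8
x5_1 x5_2
x5_1 x6_1
x5_2 x5_3
x5_3 x5_4
x5_3 x6_3
x5_4 x5_5
x5_4 x6_4
x5_5 x5_6
x5_5 x6_5
x5_7 x5_8
x5_8 x6_8
x6_1 x6_2
x6_1 x7_1
x6_2 x7_2
x6_3 x6_4
x6_3 x7_3
x6_4 x6_5
x6_4 x7_4
x6_5 x6_6
x6_5 x7_5
x6_6 x6_7
x6_6 x7_6
x6_7 x6_8
x6_7 x7_7
x6_8 x7_8
x7_1 x7_2
x7_1 x8_1
x7_2 x7_3
x7_2 x8_2
x7_3 x7_4
x7_4 x7_5
x7_4 x8_4
x7_5 x7_6
x7_5 x8_5
x7_6 x7_7
x7_6 x8_6
x7_7 x7_8
x7_7 x8_7
x7_8 x8_8
x8_1 x8_2
x8_3 x8_4
x8_4 x8_5
x8_6 x8_7
x8_7 x8_8
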