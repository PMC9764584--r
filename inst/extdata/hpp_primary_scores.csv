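# Primary-variable scores (X1-X10) of 37 county/district health promotion policies
# from the Sichuan pilot programme; each score is the published 3-decimal mean of
# that dimension's binary indicators, and each row sums to the policy's PMC index.
policy_id,X1,X2,X3,X4,X5,X6,X7,X8,X9,X10
P1,0.857,0.500,0.500,0.250,0.800,1.000,1.000,0.250,1.000,1.000
P2,0.857,0.250,0.750,0.250,0.800,0.833,0.800,0.250,0.600,1.000
P3,0.714,0.500,0.250,0.250,0.800,0.833,1.000,0.250,0.600,1.000
P4,0.857,0.250,0.250,0.250,0.600,1.000,1.000,0.250,1.000,1.000
P5,1.000,0.750,0.750,0.500,1.000,1.000,1.000,0.250,1.000,1.000
P6,0.429,0.500,0.250,0.500,0.600,1.000,1.000,0.250,1.000,1.000
P7,1.000,1.000,1.000,0.750,1.000,1.000,1.000,0.250,1.000,1.000
P8,0.857,0.250,0.500,0.250,0.800,1.000,1.000,0.250,1.000,1.000
P9,1.000,1.000,0.500,0.500,1.000,1.000,1.000,0.250,1.000,1.000
P10,0.429,1.000,0.750,0.750,0.600,1.000,1.000,0.250,1.000,1.000
P11,0.571,0.250,0.500,0.500,1.000,0.833,0.600,0.250,1.000,1.000
P12,0.714,1.000,1.000,0.750,0.800,1.000,1.000,0.250,1.000,1.000
P13,0.857,0.250,0.250,0.250,0.800,1.000,0.800,0.250,1.000,1.000
P14,0.857,0.250,0.500,0.250,0.800,0.833,0.600,0.250,1.000,1.000
P15,0.714,0.250,0.250,0.500,0.600,0.667,0.600,0.500,0.600,1.000
P16,1.000,0.250,0.250,0.250,0.800,1.000,0.800,0.250,1.000,1.000
P17,0.714,1.000,0.750,0.750,0.600,1.000,1.000,0.250,1.000,1.000
P18,1.000,1.000,0.750,0.500,1.000,1.000,1.000,0.250,1.000,1.000
P19,0.714,0.500,0.000,0.250,0.600,0.833,0.800,0.250,1.000,1.000
P20,0.857,1.000,0.500,0.500,1.000,1.000,1.000,0.250,1.000,1.000
P21,0.857,0.500,0.500,0.500,0.800,1.000,1.000,0.250,1.000,1.000
P22,0.571,0.250,0.750,0.250,0.600,1.000,0.800,0.250,0.800,1.000
P23,0.429,1.000,0.750,0.750,0.600,1.000,1.000,0.250,1.000,1.000
P24,0.429,0.500,0.250,0.500,0.600,1.000,1.000,0.250,1.000,1.000
P25,0.857,0.500,0.750,0.000,0.800,1.000,1.000,0.250,0.800,1.000
P26,0.714,0.500,0.250,0.000,0.800,1.000,0.800,0.250,1.000,1.000
P27,0.857,0.500,0.250,0.250,0.800,1.000,0.800,0.250,1.000,1.000
P28,0.429,0.750,0.750,0.500,0.600,1.000,1.000,0.250,1.000,1.000
P29,0.714,0.750,0.750,0.250,0.800,1.000,1.000,0.250,1.000,1.000
P30,0.571,1.000,0.750,0.500,0.600,1.000,1.000,0.250,1.000,1.000
P31,0.857,0.500,1.000,0.500,1.000,1.000,1.000,0.250,1.000,1.000
P32,0.429,1.000,0.750,0.750,0.600,1.000,1.000,0.250,1.000,1.000
P33,0.571,0.250,0.250,0.000,0.600,0.500,0.400,0.250,0.200,1.000
P34,1.000,0.500,0.750,0.750,1.000,1.000,1.000,0.250,1.000,1.000
P35,0.571,0.500,0.500,0.750,0.600,1.000,1.000,0.250,0.000,1.000
P36,0.714,0.500,0.250,0.000,1.000,1.000,1.000,0.250,1.000,1.000
P37,0.714,0.500,0.750,0.250,0.800,1.000,1.000,0.250,1.000,1.000
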