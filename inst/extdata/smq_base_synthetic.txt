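Anaphylaxis
Anaphylactic reaction
Anaphylactic shock
Urticaria, generalized
Erythema, generalized
Angioedema
Pruritus, generalized
Skin rash
Prickle sensation, generalized
Urticaria at injection site
Eyes red and itchy
Generalized pruritus with skin rash
Generalized pruritus without skin rash
Wheeze, bilateral
Stridor
Upper airway swelling
Difficulty breathing
Sensation of throat closure
SYN:000005
SYN:000007
SYN:000011
SYN:000013
SYN:000017
SYN:000019
SYN:000023
SYN:000029
SYN:000031
SYN:000037
SYN:000041
SYN:000043
SYN:000047
SYN:000053
SYN:000059
SYN:000061
SYN:000067
SYN:000071
SYN:000073
SYN:000079
SYN:000083
SYN:000089
SYN:000097
SYN:000101
SYN:000103
SYN:000107
SYN:000109
SYN:000113
SYN:000127
SYN:000131
SYN:000137
SYN:000139
SYN:000149
SYN:000151
SYN:000157
SYN:000163
SYN:000167
SYN:000173
SYN:000179
SYN:000181
SYN:000191
SYN:000193
SYN:000197
SYN:000199
SYN:000211
SYN:000223
SYN:000227
SYN:000229
SYN:000233
SYN:000239
SYN:000241
SYN:000251
SYN:000257
SYN:000263
SYN:000269
SYN:000271
SYN:000277
SYN:000281
SYN:000283
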