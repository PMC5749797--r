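VV  synthetic example matrices in TRANSFAC flat format
XX
//
AC  M00005
XX
ID  V$AP4_01
XX
P0      A      C      G      T
01      2     18      1      2
02     21      0      1      1
03      0      1     20      2
04      1     19      1      2
05      0      2      1     20
06     18      1      3      1
XX
//
AC  M00280
XX
ID  V$RFX1_01
XX
PO      A      C      G      T
01     14      2      4      3
02      1      1     19      2
03      2      1      1     19
04     16      3      2      2
05      2     17      1      3
06      3      2     16      2
07      1      2      2     18
08     15      2      3      3
XX
//
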