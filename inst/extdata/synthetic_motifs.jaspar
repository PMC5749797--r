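>MA0474.1 Erg
A  [  4 17  0  0 25  1  3  7 ]
C  [ 16  0  1  0  0 21  2  5 ]
G  [  4  3 24  0  0  2 19  6 ]
T  [  1  5  0 25  0  1  1  7 ]
>MA0506.1 NRF1
A  [  2  0 22  1  0  3  0 20  2  1 ]
C  [ 20  3  1  0 24  2  1  2 19  3 ]
G  [  2 21  1  0  0 19  2  1  3 18 ]
T  [  1  1  1 24  1  1 22  2  1  3 ]
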