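
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
             A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
    1 E   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  1  0  0  1  3 51  0  8  0  1  5  2  7  5  0  5  1  0  9  0.30     0.10
    2 V   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  2  1  4  1  1  0  0  5  0  1 15  1  4  6  1  0  1  8 48  0.30     0.10
    3 S   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    2  1  3  1  6  1  2  2  5  3  4  2  7  0  0 58  2  0  0  0  0.30     0.10
    4 V   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  3  0  6  1  5  6  8  1  6  0  4  0  1  4  1  1  0  1 53  0.30     0.10
    5 E   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    4  0  0  2  3  2 48  0  3  0  0  0  0 11  0  1 17  0  3  4  0.30     0.10
    6 W   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0.30     0.10
    7 G   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  1  0  2 10  1  1 45  1  1 12 17  4  3  1  0  1  0  0  1  0.30     0.10
    8 N   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    1  0 51  7  1  5  1  1  0 17  0  5  1  4  3  2  0  0  0  1  0.30     0.10
    9 A   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0   26  0  0  4  1  8  0  5  0 13  1  0 12  3 11  0  4  0  2  7  0.30     0.10
   10 F   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    1  6  1  2  4  2  0  1  2  3  3  1  0 64  0  1  2  4  0  3  0.30     0.10
   11 G   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    0  0  0  0  0 15 13 60  0  1  1  0  4  0  0  1  2  0  0  1  0.30     0.10
   12 E   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    1  3  1  0  2  0 58  1  1  1  1  1  3  1  2  2  1  0  2 18  0.30     0.10
   13 Q   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    1  0  3  1  3 45  2  0  0  0 20  0  0  4  6  0  6  0  6  2  0.30     0.10
   14 P   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    1  3  8  7  0  0  8  1  0  2 24  0  1  1 37  0  0  1  4  0  0.30     0.10
   15 C   0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0    3  0  3  0 63  0  6  0  0  2  1  4  7  3  2  2  1  1  0  1  0.30     0.10

                      K         Lambda
Standard Ungapped    0.1337     0.3176
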