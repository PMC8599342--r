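>OCT4 OCT4_synthetic
A [ 82  2  2  2 94 94 94  6 ]
C [  6  2  2 94  2  2  2  6 ]
G [  6  2 94  2  2  2  2  6 ]
T [  6 94  2  2  2  2  2 82 ]
>SOX2 SOX2_synthetic
A [ 82 94  2 94 94  2  2  6 ]
C [  6  2 94  2  2  2  2  6 ]
G [  6  2  2  2  2  2 94 82 ]
T [  6  2  2  2  2 94  2  6 ]
>OCT4_SOX2 OCT4_SOX2_synthetic
A [  6  6  6  2  2 94  2 94 94  2 94 82  6  6 ]
C [  6  6  6  2 94  2  2  2  2 94  2  6  6  6 ]
G [  6  6  6 94  2  2  2  2  2  2  2  6  6 82 ]
T [ 82 82 82  2  2  2 94  2  2  2  2  6 82  6 ]
>TEAD1 TEAD1_synthetic
A [  6 82  2 94  2  2  2  2 82  6 ]
C [ 82  6 94  2  2  2 94 94  6 82 ]
G [  6  6  2  2  2  2  2  2  6  6 ]
T [  6  6  2  2 94 94  2  2  6  6 ]
>TEAD2 TEAD2_synthetic
A [  6  6  2 94  2  2  2  2  6 82 ]
C [  6  6 94  2  2  2 94 94  6  6 ]
G [  6 82  2  2  2  2  2  2 82  6 ]
T [ 82  6  2  2 94 94  2  2  6  6 ]
>TEAD3 TEAD3_synthetic
A [ 82 82  2 94  2  2  2  2  6  6 ]
C [  6  6 94  2  2  2 94 94  6 82 ]
G [  6  6  2  2  2  2  2  2  6  6 ]
T [  6  6  2  2 94 94  2  2 82  6 ]
>TEAD4 TEAD4_synthetic
A [  6  6  2 94  2  2  2  2 82  6 ]
C [  6  6 94  2  2  2 94 94  6  6 ]
G [ 82  6  2  2  2  2  2  2  6 82 ]
T [  6 82  2  2 94 94  2  2  6  6 ]
>ZIC3 ZIC3_synthetic
A [  6  6  2  2  2  2  2  2  6  6 ]
C [ 82 82 94  2 94  2  2  2  6  6 ]
G [  6  6  2 94  2  2 94  2 82 82 ]
T [  6  6  2  2  2 94  2 94  6  6 ]
>KLF4 KLF4_synthetic
A [  6  2  2  2  2  2  2  2  2  6 ]
C [  6  2  2  2  2  2  2  2  2 82 ]
G [ 82 94 94 94  2 94 94 94 94  6 ]
T [  6  2  2  2 94  2  2  2  2  6 ]
>CTCF CTCF_synthetic
A [  6  6  2  2  2 94  2  2  2  2  2  2 82  6 ]
C [ 82 82  2 94  2  2  2  2  2  2  2 94  6  6 ]
G [  6  6 94  2 94  2 94 94  2 94 94  2  6 82 ]
T [  6  6  2  2  2  2  2  2 94  2  2  2  6  6 ]
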