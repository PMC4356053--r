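>SYN0001.1 EGR1_SYN
A [ 1 1 1 1 1 1 1 1 1 1 ]
C [ 1 97 1 1 1 1 1 97 1 1 ]
G [ 97 1 97 97 97 97 97 1 97 97 ]
T [ 1 1 1 1 1 1 1 1 1 1 ]
>SYN0002.1 TFAP2A_SYN
A [ 1 1 1 1 10 70 1 1 1 ]
C [ 1 97 90 90 80 10 1 1 97 ]
G [ 97 1 8 8 5 10 97 97 1 ]
T [ 1 1 1 1 5 10 1 1 1 ]
>SYN0003.1 ETS1_SYN
A [ 80 1 85 1 1 97 97 1 5 1 ]
C [ 10 90 5 1 1 1 1 1 5 1 ]
G [ 5 5 5 97 97 1 1 90 80 90 ]
T [ 5 4 5 1 1 1 1 8 10 8 ]
>SYN0004.1 MYCN_SYN
A [ 1 1 97 1 1 1 5 1 ]
C [ 1 97 1 97 1 1 5 1 ]
G [ 97 1 1 1 97 1 85 97 ]
T [ 1 1 1 1 1 97 5 1 ]
>SYN0005.1 ARNT_SYN
A [ 5 90 1 1 1 5 10 1 ]
C [ 5 5 97 1 1 1 80 97 ]
G [ 5 4 1 97 1 90 5 1 ]
T [ 85 1 1 1 97 4 5 1 ]
>SYN0006.1 AP1_SYN
A [ 5 1 97 1 1 5 90 1 ]
C [ 5 1 1 97 1 90 5 1 ]
G [ 5 97 1 1 1 4 4 1 ]
T [ 85 1 1 1 97 1 1 97 ]
>SYN0007.1 NFKB_SYN
A [ 1 1 1 90 1 5 1 1 1 1 ]
C [ 1 1 1 5 90 1 1 1 97 97 ]
G [ 97 97 97 4 5 1 1 1 1 1 ]
T [ 1 1 1 1 4 93 97 97 1 1 ]
>SYN0008.1 MEF2_SYN
A [ 1 1 90 1 1 1 97 1 90 1 ]
C [ 97 1 5 1 1 1 1 1 5 1 ]
G [ 1 1 4 1 1 1 1 1 4 97 ]
T [ 1 97 1 97 97 97 1 97 1 1 ]
>SYN0009.1 CTCF_SYN
A [ 1 1 1 1 1 1 1 1 5 1 ]
C [ 97 97 1 97 1 5 1 1 5 1 ]
G [ 1 1 97 1 97 90 97 1 85 97 ]
T [ 1 1 1 1 1 4 1 97 5 1 ]
>SYN0010.1 GATA_SYN
A [ 90 1 97 1 97 97 1 90 ]
C [ 4 1 1 1 1 1 1 4 ]
G [ 5 97 1 1 1 1 97 5 ]
T [ 1 1 1 97 1 1 1 1 ]
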