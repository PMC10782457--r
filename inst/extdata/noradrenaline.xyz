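23
synthetic approximate (R)-noradrenaline (C8H11NO3) geometry; used for basis counting only
C  1.396  0.000  0.000
C  0.698  1.209  0.000
C -0.698  1.209  0.000
C -1.396  0.000  0.000
C -0.698 -1.209  0.000
C  0.698 -1.209  0.000
H  1.235  2.139  0.000
H -1.235 -2.139  0.000
H  1.235 -2.139  0.000
O -1.380  2.390  0.000
O -2.760  0.000  0.000
H -0.950  3.250  0.300
H -3.300  0.800  0.300
C  2.920  0.000  0.300
O  3.450  1.200  0.100
H  4.400  1.200  0.200
H  3.300 -0.700  1.000
C  3.620 -0.750 -0.900
N  5.000 -0.800 -0.800
H  3.200 -1.700 -1.000
H  3.300 -0.200 -1.800
H  5.400 -1.600 -1.300
H  5.500  0.000 -1.000
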