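# Element fallback van der Waals radii (A); conventional values,
# used only for atoms absent from the residue library.
C 1.80
N 1.60
O 1.52
S 1.80
P 1.80
SE 1.90
F 1.47
CL 1.75
BR 1.85
I 1.98
FE 1.80
ZN 1.39
MG 1.73
CA 2.00
NA 2.27
K 2.75
MN 1.80
CU 1.40
CO 1.80
NI 1.63
SI 2.10
B 1.92
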