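Kupffer:
- CD68
- CD163
- LYZ
- C1QA
- AIF1
T:
- CD3D
- CD2
- IL7R
- TRBC2
- CD69
B_Plasma:
- IGKC
- JCHAIN
- CD79A
- CD27
- CD74
NK_other:
- CD4
- CD8A
- ITGAM
- NKG7
- KLRD1
- PRF1
- CD7
- TRDC
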