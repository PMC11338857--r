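# Nitroxoline: hydrogen-suppressed molecular graph (14 atoms, 15 bonds)
O1 C2
C2 C3
C3 C4
C4 C5
C5 N6
N6 O7
N6 O8
C5 C9
C9 C10
C10 C11
C11 C12
C12 N13
N13 C14
C14 C2
C14 C9
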