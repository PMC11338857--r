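# Wortmannin: hydrogen-suppressed molecular graph (31 atoms, 35 bonds)
C1 O1
O1 C2
C2 O2
C2 C3
C3 C4
C4 O3
O3 C5
C5 C19
C3 C19
C5 C6
C6 O4
C6 C7
C7 C18
C7 C16
C18 C8
C18 C13
C8 C19
C8 C1
C9 O5
C9 C21
C9 C16
C21 C20
C20 C10
C10 C11
C10 C16
C10 C12
C12 C13
C13 O6
O6 C14
C14 O7
C14 C15
C16 C17
C1 C22
C22 O8
O8 C23
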