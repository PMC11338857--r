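# Vesnarinone: hydrogen-suppressed molecular graph (29 atoms, 32 bonds)
C1 O2
O2 C3
C3 C4
C4 C5
C5 C6
C6 C7
C7 O8
C7 N9
N9 C10
C10 C11
C11 N12
N12 C13
C13 C14
C14 C15
C15 C16
C16 C17
C17 C18
C17 C19
C19 C20
C20 C21
C21 O22
C21 N23
N12 C24
C24 C25
C6 C26
C26 C27
C27 O28
O28 C29
C27 C3
C25 N9
C18 C13
N23 C16
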