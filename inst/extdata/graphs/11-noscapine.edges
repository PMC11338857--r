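# Noscapine: hydrogen-suppressed molecular graph (30 atoms, 34 bonds)
C1 N2
N2 C3
C3 C4
C4 C5
C5 C6
C6 C7
C7 O8
O8 C9
C9 O10
O10 C11
C11 C12
C12 O13
O13 C14
C12 C15
C15 C16
C16 C17
C17 O18
O18 C19
C19 O20
C19 C21
C21 C22
C22 C23
C23 C24
C24 C25
C25 O26
O26 C27
C25 C28
C28 O29
O29 C30
C16 N2
C22 C17
C15 C5
C28 C21
C11 C7
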