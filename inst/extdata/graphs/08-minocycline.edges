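# Minocycline: hydrogen-suppressed molecular graph (35 atoms, 38 bonds)
C1 N2
N2 C3
N2 C4
C4 C5
C5 C6
C6 C7
C7 C8
C8 C9
C9 C10
C10 C11
C11 C12
C12 C13
C13 C14
C12 N15
N15 C16
N15 C17
C11 O18
C10 C19
C19 O20
C19 C21
C21 C22
C22 C23
C23 O24
C23 C25
C25 O26
C25 C27
C27 C28
C28 O29
C27 C30
C30 O31
C30 N32
C22 O33
C28 C4
C23 C5
C21 C7
C14 C9
C5 O34
C7 O35
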