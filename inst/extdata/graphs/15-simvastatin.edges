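# Simvastatin: hydrogen-suppressed molecular graph (31 atoms, 33 bonds)
C1 C2
C2 C3
C3 C4
C3 C5
C3 C6
C6 O7
C6 O8
O8 C9
C9 C10
C10 C11
C11 C12
C11 C13
C13 C14
C14 C15
C15 C16
C16 C17
C17 C18
C17 C19
C19 C20
C20 C21
C21 C22
C22 C23
C23 C24
C24 O25
C24 C26
C26 C27
C27 O28
C27 O29
C19 C30
C30 C9
C30 C14
O29 C22
C30 O31
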