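# Thiocolchicoside: hydrogen-suppressed molecular graph (39 atoms, 42 bonds)
C1 C2
C2 O3
C2 N4
N4 C5
C5 C6
C6 C7
C7 C8
C8 C9
C9 C10
C10 O11
O11 C12
C12 O13
O13 C14
C14 C15
C15 O16
C14 C17
C17 O18
C17 C19
C19 O20
C19 C21
C21 O22
C10 C23
C23 O24
O24 C25
C23 C26
C26 O27
O27 C28
C26 C29
C29 C30
C30 C31
C31 C32
C32 C33
C33 S34
S34 C35
C33 C36
C36 O37
C36 C38
C38 C39
C39 C5
C29 C8
C39 C30
C21 C12
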