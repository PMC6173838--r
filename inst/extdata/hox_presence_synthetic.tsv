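gene	Pangasianodon	Danio
A1a	P	P
A2a	A	Ψ
A2b	P	P
A3a	P	P
A4a	P	P
A5a	A	P
A7a	A	Ψ
A9a	P	P
A9b	P	P
A10a	A	Ψ
A10b	P	P
A11a	A	P
A11b	P	P
A13a	P	P
A13b	P	P
B1a	P	P
B1b	P	P
B2a	P	P
B3a	P	P
B3b	P	A
B4a	P	P
B5a	P	P
B5b	P	P
B6a	P	P
B6b	P	P
B7a	P	P
B8a	P	P
B8b	P	P
B9a	P	P
B10a	A	P
B13a	P	P
C1a	P	P
C1b	P	P
C3a	P	P
C4a	P	P
C4b	P	A
C5a	P	P
C5b	P	A
C6a	P	P
C6b	P	P
C8a	P	P
C8b	A	A
C9a	P	A
C10a	P	P
C10b	A	A
C11a	P	P
C11b	P	P
C12a	P	P
C12b	P	P
C13a	P	P
C13b	P	P
D1a	P	A
D3a	P	P
D4a	P	P
D4b	A	A
D9a	P	P
D9b	A	A
D10a	P	P
D11a	P	P
D11b	A	A
D12a	P	P
D13a	P	P
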