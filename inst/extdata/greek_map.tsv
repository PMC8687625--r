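greek	latin
α	A
β	B
γ	G
δ	D
ε	E
κ	K
λ	L
μ	M
σ	S
τ	T
ω	O
Α	A
Β	B
Γ	G
Δ	D
Κ	K
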