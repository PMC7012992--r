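[meta]
name = "daphnia"

[space]
dim = 1
lower = [0.5]
upper = [2.5]
x_b = [0.5]

[atoms]
f = ""

[growth]
expr = ["-0.5 * x + f*(1)"]

[death]
expr = "0.1"

[[birth]]
rate = "f*(0.75 * x^2)"
state = [0.5]

[[output]]
expr = "x^3"

[[output]]
expr = "x^2"
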