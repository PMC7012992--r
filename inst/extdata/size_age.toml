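[meta]
name = "size_age"

[space]
dim = 2
lower = [0, 0]
upper = [2, 3]
x_b = [0.5, 0]

[atoms]
a = ""
b = ""
c = ""
f = ""
mu0 = ""

[growth]
expr = ["a*(1) + b*(x1)", "c*(1)"]

[death]
expr = "mu0*(1)"

[[birth]]
rate = "f*(x1^2 + -(x1^2 * exp(-x2)))"
state = [0.5, 0]

[[output]]
expr = "f*(x1^2 + -(x1^2 * exp(-x2)))"
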