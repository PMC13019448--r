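#dynamic::start
X1
X2
X3
X4
X5
#dynamic::end

#static::start
E1
E2
E3
#static::end

#reactions::start
r0::[] --> X1
r1::X1 --> X2
r2::X2 --> X3
r3::X3 --> X4
r4::X4 --> []
r5::X3 --> X5
#reactions::end

#kinetics::start
r0::[]
r1::X1^1, E1^1, X4^-0.5
r2::X2^1, E2^1
r3::X3^1, E3^1
r4::X4^1
r5::X3^1
#kinetics::end

#alpha::start
r0 = 0
r1 = 10
r2 = 10
r3 = 10
r4 = 3
r5 = 0.10000000000000001
#alpha::end

#initial::start
X1 = 0.10000000000000001
X2 = 0.10000000000000001
X3 = 0.10000000000000001
X4 = 0.10000000000000001
X5 = 0.10000000000000001
#initial::end

#staticvalues::start
E1 = 1
E2 = 1
E3 = 1
#staticvalues::end

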