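[metadata]
author = "bstkit"
version = "1.0"
description = "branched pathway with dual feedback"

[model]
dynamic_species = [
    "A",
    "B",
    "C",
    "D",
    "E",
]
static_species = [
    "E3",
    "E4",
]
reactions = [
    "r0::[] --> A",
    "r1::A --> B",
    "r2::B --> C",
    "r3::C --> D",
    "r4::C --> E",
    "r5::D --> []",
    "r6::E --> []",
]
kinetics = [
    "r0::[]",
    "r1::A^1, E^-0.5",
    "r2::B^1, D^-0.5",
    "r3::C^1, E3^1",
    "r4::C^1, E4^1",
    "r5::D^1",
    "r6::E^1",
]

[model.alpha]
r0 = 1
r1 = 1
r2 = 1
r3 = 1
r4 = 1
r5 = 1
r6 = 1

[model.initial]
A = 0.10000000000000001
B = 0.10000000000000001
C = 0.10000000000000001
D = 0.10000000000000001
E = 0.10000000000000001

[model.static_values]
E3 = 1
E4 = 1
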