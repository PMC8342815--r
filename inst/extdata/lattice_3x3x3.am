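# AmiraMesh 3D ASCII 2.0
# synthetic 3x3x3 test lattice; values enumerate x-fastest order

define Lattice 3 3 3

Parameters {
    Content "3x3x3 byte, uniform coordinates",
    BoundingBox 0 2 0 2 0 2,
    CoordType "uniform"
}

Lattice { byte Data } @1

@1
0 1 2
3 4 5
6 7 8
9 10 11
12 13 14
15 16 17
18 19 20
21 22 23
24 25 26
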