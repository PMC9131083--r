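# example snake text fixture (documented dialect)
# blocks start with "snake <id>"; vertex rows are: index x y z intensity
# coordinates in pixels; optional trailing "junctions" section with x y z rows
snake 0
0 10.5 20.0 1.0 100
1 12.5 20.5 1.0 110
2 14.5 21.0 1.0 105
snake 1
0 30.0 40.0 2.0 80
1 32.0 40.0 2.0 85
2 34.0 40.5 2.0 90
3 36.0 41.0 2.0 88
junctions
14.5 21.0 1.0
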