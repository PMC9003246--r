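# vtk DataFile Version 3.0
unit cube split into five tetrahedra
ASCII
DATASET UNSTRUCTURED_GRID
POINTS 8 double
0 0 0
1 0 0
0 1 0
1 1 0
0 0 1
1 0 1
0 1 1
1 1 1
CELLS 5 25
4 0 1 2 4
4 1 2 3 7
4 1 4 5 7
4 2 4 6 7
4 1 2 4 7
CELL_TYPES 5
10
10
10
10
10
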