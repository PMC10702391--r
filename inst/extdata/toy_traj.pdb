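MODEL        1
ATOM      1  CA  SER A 366       0.000   0.000   0.000  1.00  0.00
ATOM      2  CA  ASP A 400       3.200   1.100   0.500  1.00  0.00
ATOM      3  CA  GLY A 442       4.800   3.600   1.200  1.00  0.00
ATOM      4  CA  ASP A 487       8.100  -2.000   0.800  1.00  0.00
HETATM    5  NA  NA  A 601       9.000  -1.500   1.900  1.00  0.00
HETATM    6  CA  ASP A 700       2.500   2.200   1.000  1.00  0.00
HETATM    7  CB  ASP A 700       3.100   3.400   0.200  1.00  0.00
HETATM    8  OD1 ASP A 700       4.000   3.900  -0.600  1.00  0.00
ATOM      9  CA  SER B 366      20.000   0.000   0.000  1.00  0.00
ENDMDL
MODEL        2
ATOM      1  CA  SER A 366       1.500   1.500   1.500  1.00  0.00
ATOM      2  CA  ASP A 400       4.700   2.600   2.000  1.00  0.00
ATOM      3  CA  GLY A 442       6.300   5.100   2.700  1.00  0.00
ATOM      4  CA  ASP A 487       9.600  -0.500   2.300  1.00  0.00
HETATM    5  NA  NA  A 601      10.500   0.000   3.400  1.00  0.00
HETATM    6  CA  ASP A 700       4.000   3.700   2.500  1.00  0.00
HETATM    7  CB  ASP A 700       4.600   4.900   1.700  1.00  0.00
HETATM    8  OD1 ASP A 700       5.500   5.400   0.900  1.00  0.00
ATOM      9  CA  SER B 366      21.500   1.500   1.500  1.00  0.00
ENDMDL
END
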