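ATOM      1  CB  ASP A   1       0.000   0.000   0.000  1.00  0.00           C  
ATOM      2  HB1 ASP A   1       1.061  -0.238  -0.025  1.00  0.00           H  
ATOM      3  HB2 ASP A   1      -0.579  -0.857  -0.335  1.00  0.00           H  
ATOM      4  CG  ASP A   1      -0.403   0.356   1.422  1.00  0.00           C  
ATOM      5  OD1 ASP A   1      -0.246  -0.505   2.312  1.00  0.00           O  
ATOM      6  OD2 ASP A   1      -0.873   1.492   1.635  1.00  0.00           O  
ATOM      7  CB  ASP A   2      10.000   0.000   0.000  1.00  0.00           C  
ATOM      8  HB1 ASP A   2       9.162   0.649  -0.242  1.00  0.00           H  
ATOM      9  HB2 ASP A   2      10.516  -0.292  -0.911  1.00  0.00           H  
ATOM     10  CG  ASP A   2      10.965   0.743   0.910  1.00  0.00           C  
ATOM     11  OD1 ASP A   2      11.486   1.795   0.484  1.00  0.00           O  
ATOM     12  OD2 ASP A   2      11.194   0.267   2.041  1.00  0.00           O  
END   
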