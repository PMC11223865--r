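ATOM      1  P    DA D   6      -4.000   0.000  -2.500  1.00  0.00           P  
ATOM      2  C1'  DA D   6      -4.000   0.000  -1.000  1.00  0.00           C  
ATOM      3  N1   DA D   6      -4.000   0.000   0.000  1.00  0.00           N  
ATOM      4  P    DT D   7       0.000   0.000  -2.500  1.00  0.00           P  
ATOM      5  C1'  DT D   7       0.000   0.000  -1.000  1.00  0.00           C  
ATOM      6  N1   DT D   7       0.000   0.000   0.000  1.00  0.00           N  
ATOM      7  P    DG D   8       4.000   0.000  -2.500  1.00  0.00           P  
ATOM      8  C1'  DG D   8       4.000   0.000  -1.000  1.00  0.00           C  
ATOM      9  N1   DG D   8       4.000   0.000   0.000  1.00  0.00           N  
ATOM     10  P    DC D   9       8.000   0.000  -2.500  1.00  0.00           P  
ATOM     11  C1'  DC D   9       8.000   0.000  -1.000  1.00  0.00           C  
ATOM     12  N1   DC D   9       8.000   0.000   0.000  1.00  0.00           N  
ATOM     13  N   ARG A 137       1.794   5.979   3.382  1.00  0.00           N  
ATOM     14  CA  ARG A 137       1.491   4.969   2.811  1.00  0.00           C  
ATOM     15  CB  ARG A 137       0.733   2.442   1.382  1.00  0.00           C  
ATOM     16  N   ASN A 289       5.298   6.474   3.114  1.00  0.00           N  
ATOM     17  CA  ASN A 289       5.084   5.409   2.602  1.00  0.00           C  
ATOM     18  CB  ASN A 289       4.551   2.749   1.323  1.00  0.00           C  
ATOM     19  N   THR A 291       0.793   6.382   2.763  1.00  0.00           N  
ATOM     20  CA  THR A 291       0.657   5.288   2.290  1.00  0.00           C  
ATOM     21  CB  THR A 291       0.317   2.553   1.105  1.00  0.00           C  
ATOM     22  N   SER A 294       4.425   7.119   2.903  1.00  0.00           N  
ATOM     23  CA  SER A 294       4.359   6.010   2.451  1.00  0.00           C  
ATOM     24  CB  SER A 294       4.193   3.236   1.320  1.00  0.00           C  
ATOM     25  N   ARG A 351       0.000   7.428   2.971  1.00  0.00           N  
ATOM     26  CA  ARG A 351       0.000   6.314   2.525  1.00  0.00           C  
ATOM     27  CB  ARG A 351       0.000   3.528   1.411  1.00  0.00           C  
ATOM     28  N   LYS A 140       3.514   8.136   3.318  1.00  0.00           N  
ATOM     29  CA  LYS A 140       3.581   7.027   2.866  1.00  0.00           C  
ATOM     30  CB  LYS A 140       3.746   4.253   1.734  1.00  0.00           C  
ATOM     31  N   GLU A 300      -1.099   8.844   3.829  1.00  0.00           N  
ATOM     32  CA  GLU A 300      -0.963   7.750   3.355  1.00  0.00           C  
ATOM     33  CB  GLU A 300      -0.623   5.015   2.171  1.00  0.00           C  
ATOM     34  N   GLY A 352       1.974  10.109   4.863  1.00  0.00           N  
ATOM     35  CA  GLY A 352       2.187   9.045   4.351  1.00  0.00           C  
ATOM     36  CB  GLY A 352       2.720   6.385   3.072  1.00  0.00           C  
ATOM     37  N   TYR A 410      -3.335  11.116   6.288  1.00  0.00           N  
ATOM     38  CA  TYR A 410      -3.032  10.106   5.717  1.00  0.00           C  
ATOM     39  CB  TYR A 410      -2.274   7.579   4.288  1.00  0.00           C  
END   
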