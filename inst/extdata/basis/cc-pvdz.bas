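! cc-pVDZ correlation-consistent basis (Dunning). Spherical d functions.
element H
S 4
  13.01000000   0.01968500
   1.96200000   0.13797700
   0.44460000   0.47814800
   0.12200000   0.50124000
S 1
   0.12200000   1.00000000
P 1
   0.72700000   1.00000000
element C
S 9
6665.00000000   0.00069200
1000.00000000   0.00532900
 228.00000000   0.02707700
  64.71000000   0.10171800
  21.06000000   0.27474000
   7.49500000   0.44856400
   2.79700000   0.28507400
   0.52150000   0.01520400
   0.15960000  -0.00319100
S 9
6665.00000000  -0.00014600
1000.00000000  -0.00115400
 228.00000000  -0.00572500
  64.71000000  -0.02331200
  21.06000000  -0.06395500
   7.49500000  -0.14998100
   2.79700000  -0.12726200
   0.52150000   0.54452900
   0.15960000   0.58049600
S 1
   0.15960000   1.00000000
P 4
   9.43900000   0.03810900
   2.00200000   0.20948000
   0.54560000   0.50855700
   0.15170000   0.46884200
P 1
   0.15170000   1.00000000
D 1
   0.55000000   1.00000000
element N
S 9
9046.00000000   0.00070000
1357.00000000   0.00538900
 309.30000000   0.02740600
  87.73000000   0.10320700
  28.56000000   0.27872300
  10.21000000   0.44854000
   3.83800000   0.27823800
   0.74660000   0.01544000
   0.22480000  -0.00286400
S 9
9046.00000000  -0.00015300
1357.00000000  -0.00120800
 309.30000000  -0.00599200
  87.73000000  -0.02454400
  28.56000000  -0.06745900
  10.21000000  -0.15807800
   3.83800000  -0.12183100
   0.74660000   0.54900300
   0.22480000   0.57881500
S 1
   0.22480000   1.00000000
P 4
  13.55000000   0.03991900
   2.91700000   0.21716900
   0.79730000   0.51031900
   0.21850000   0.46220600
P 1
   0.21850000   1.00000000
D 1
   0.81700000   1.00000000
element O
S 9
11720.00000000  0.00071000
 1759.00000000  0.00547000
  400.80000000  0.02783700
  113.70000000  0.10480000
   37.03000000  0.28306200
   13.27000000  0.44871900
    5.02500000  0.27095200
    1.01300000  0.01545800
    0.30230000 -0.00258500
S 9
11720.00000000 -0.00016000
 1759.00000000 -0.00126300
  400.80000000 -0.00626700
  113.70000000 -0.02571600
   37.03000000 -0.07092400
   13.27000000 -0.16541100
    5.02500000 -0.11695500
    1.01300000  0.55736800
    0.30230000  0.57275900
S 1
    0.30230000  1.00000000
P 4
   17.70000000  0.04301800
    3.85400000  0.22891300
    1.04600000  0.50872800
    0.27530000  0.46053100
P 1
    0.27530000  1.00000000
D 1
    1.18500000  1.00000000
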