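"depression_deg","broadband_w_m2"
0,1.21049
0.5,0.789346
1,0.514722
1.5,0.335643
2,0.218868
2.5,0.142721
3,0.0930662
3.5,0.0606872
4,0.0395733
4.5,0.0258052
5,0.0168272
5.5,0.0109728
6,0.0071552
6.5,0.00466581
7,0.00304251
7.5,0.00198398
8,0.00129372
8.5,0.000843619
9,0.000550112
9.5,0.000358721
10,0.000233917
10.5,0.000152534
11,9.94652e-05
11.5,6.48598e-05
12,4.22942e-05
12.5,2.75795e-05
13,1.79842e-05
13.5,1.17272e-05
14,7.64717e-06
14.5,4.98661e-06
15,3.2517e-06
15.5,2.12039e-06
16,1.38268e-06
16.5,9.01623e-07
17,5.87936e-07
17.5,3.83385e-07
18,2.5e-07
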