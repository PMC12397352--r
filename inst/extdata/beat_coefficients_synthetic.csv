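m,n,a,b
0,0,-3.12144460259e-01,0.00000000000e+00
0,1,-4.96936406029e-01,5.22760753337e-01
0,2,-4.53777701040e-01,-8.47033932576e-02
0,3,-4.78226167996e-02,-9.65540230320e-02
0,4,8.45129293775e-03,-1.57981347556e-02
0,5,2.09157638872e-03,-2.99811232021e-04
0,6,1.42146811124e-04,1.47454497893e-04
0,7,-2.77738030348e-06,1.59140245862e-05
0,8,-9.96259488618e-07,4.85601769440e-07
1,0,-7.08675812590e-01,0.00000000000e+00
1,1,5.10222949928e-01,3.02440040737e-01
1,2,2.28519162281e-02,2.07800098211e-01
1,3,-1.72822712011e-02,-3.89790853551e-02
1,4,3.76404883575e-02,-1.52150323352e-02
1,5,1.29046642660e-02,9.34528891237e-03
1,6,-9.08115589336e-05,4.13227302667e-03
1,7,-6.78880584456e-04,4.64372714186e-04
1,8,-1.25971976613e-04,-4.54036539490e-05
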