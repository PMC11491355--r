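point,tx,ty,tz,ax,ay,az
1,7.7,-8.1,43.4,7.7,-8.2,45.3
2,-10.9,0.2,32.67,-9.7,0.7,32.0
3,-14.7,-12.6,42.7,-15.1,-11.4,43.2
4,-12.4,5.0,46.0,-11.8,5.4,46.3
5,-5.7,7.2,34.1,-4.8,8.1,35.4
6,8.5,12.8,32.3,9.9,11.6,32.1
7,-3.0,3.2,48.8,-2.3,2.4,50.0
8,12.6,-8.0,37.2,11.2,-8.6,36.4
9,-13.4,6.6,37.5,-13.2,5.5,36.9
10,2.5,4.8,48.9,1.9,5.1,49.6
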