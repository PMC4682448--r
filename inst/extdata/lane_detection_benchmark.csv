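image,width_px,height_px,lanes_total,lanes_detected
1a,1884,524,72,39
2a,1955,524,60,37
3a,1871,524,72,19
4a,1911,546,60,45
5a,1810,718,56,46
6b,1810,718,34,34
7b,473,288,32,31
8b,234,500,15,14
9b,276,574,15,15
10b,276,399,17,17
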