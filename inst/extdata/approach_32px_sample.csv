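t_us,x,y,polarity
10000,14,12,OFF
10000,15,12,OFF
10000,16,12,OFF
10000,17,12,OFF
10000,13,13,OFF
10000,18,13,OFF
10000,12,14,OFF
10000,19,14,OFF
10000,12,15,OFF
10000,19,15,OFF
10000,12,16,OFF
10000,19,16,OFF
10000,12,17,OFF
10000,19,17,OFF
10000,13,18,OFF
10000,18,18,OFF
10000,14,19,OFF
10000,15,19,OFF
10000,16,19,OFF
10000,17,19,OFF
20000,13,11,OFF
20000,14,11,OFF
20000,15,11,OFF
20000,16,11,OFF
20000,17,11,OFF
20000,18,11,OFF
20000,12,12,OFF
20000,13,12,OFF
20000,18,12,OFF
20000,19,12,OFF
20000,11,13,OFF
20000,12,13,OFF
20000,19,13,OFF
20000,20,13,OFF
20000,11,14,OFF
20000,20,14,OFF
20000,11,15,OFF
20000,20,15,OFF
20000,11,16,OFF
20000,20,16,OFF
20000,11,17,OFF
20000,20,17,OFF
20000,11,18,OFF
20000,12,18,OFF
20000,19,18,OFF
20000,20,18,OFF
20000,12,19,OFF
20000,13,19,OFF
20000,18,19,OFF
20000,19,19,OFF
20000,13,20,OFF
20000,14,20,OFF
20000,15,20,OFF
20000,16,20,OFF
20000,17,20,OFF
20000,18,20,OFF
30000,13,10,OFF
30000,14,10,OFF
30000,15,10,OFF
30000,16,10,OFF
30000,17,10,OFF
30000,18,10,OFF
30000,11,11,OFF
30000,12,11,OFF
30000,19,11,OFF
30000,20,11,OFF
30000,11,12,OFF
30000,20,12,OFF
30000,10,13,OFF
30000,21,13,OFF
30000,10,14,OFF
30000,21,14,OFF
30000,10,15,OFF
30000,21,15,OFF
30000,10,16,OFF
30000,21,16,OFF
30000,10,17,OFF
30000,21,17,OFF
30000,10,18,OFF
30000,21,18,OFF
30000,11,19,OFF
30000,20,19,OFF
30000,11,20,OFF
30000,12,20,OFF
30000,19,20,OFF
30000,20,20,OFF
30000,13,21,OFF
30000,14,21,OFF
30000,15,21,OFF
30000,16,21,OFF
30000,17,21,OFF
30000,18,21,OFF
40000,14,8,OFF
40000,15,8,OFF
40000,16,8,OFF
40000,17,8,OFF
40000,12,9,OFF
40000,13,9,OFF
40000,14,9,OFF
40000,15,9,OFF
40000,16,9,OFF
40000,17,9,OFF
40000,18,9,OFF
40000,19,9,OFF
40000,11,10,OFF
40000,12,10,OFF
40000,19,10,OFF
40000,20,10,OFF
40000,10,11,OFF
40000,21,11,OFF
40000,9,12,OFF
40000,10,12,OFF
40000,21,12,OFF
40000,22,12,OFF
40000,9,13,OFF
40000,22,13,OFF
40000,8,14,OFF
40000,9,14,OFF
40000,22,14,OFF
40000,23,14,OFF
40000,8,15,OFF
40000,9,15,OFF
40000,22,15,OFF
40000,23,15,OFF
40000,8,16,OFF
40000,9,16,OFF
40000,22,16,OFF
40000,23,16,OFF
40000,8,17,OFF
40000,9,17,OFF
40000,22,17,OFF
40000,23,17,OFF
40000,9,18,OFF
40000,22,18,OFF
40000,9,19,OFF
40000,10,19,OFF
40000,21,19,OFF
40000,22,19,OFF
40000,10,20,OFF
40000,21,20,OFF
40000,11,21,OFF
40000,12,21,OFF
40000,19,21,OFF
40000,20,21,OFF
40000,12,22,OFF
40000,13,22,OFF
40000,14,22,OFF
40000,15,22,OFF
40000,16,22,OFF
40000,17,22,OFF
40000,18,22,OFF
40000,19,22,OFF
40000,14,23,OFF
40000,15,23,OFF
40000,16,23,OFF
40000,17,23,OFF
50000,14,7,OFF
50000,15,7,OFF
50000,16,7,OFF
50000,17,7,OFF
50000,11,8,OFF
50000,12,8,OFF
50000,13,8,OFF
50000,18,8,OFF
50000,19,8,OFF
50000,20,8,OFF
50000,10,9,OFF
50000,11,9,OFF
50000,20,9,OFF
50000,21,9,OFF
50000,9,10,OFF
50000,10,10,OFF
50000,21,10,OFF
50000,22,10,OFF
50000,8,11,OFF
50000,9,11,OFF
50000,22,11,OFF
50000,23,11,OFF
50000,8,12,OFF
50000,23,12,OFF
50000,8,13,OFF
50000,23,13,OFF
50000,7,14,OFF
50000,24,14,OFF
50000,7,15,OFF
50000,24,15,OFF
50000,7,16,OFF
50000,24,16,OFF
50000,7,17,OFF
50000,24,17,OFF
50000,8,18,OFF
50000,23,18,OFF
50000,8,19,OFF
50000,23,19,OFF
50000,8,20,OFF
50000,9,20,OFF
50000,22,20,OFF
50000,23,20,OFF
50000,9,21,OFF
50000,10,21,OFF
50000,21,21,OFF
50000,22,21,OFF
50000,10,22,OFF
50000,11,22,OFF
50000,20,22,OFF
50000,21,22,OFF
50000,11,23,OFF
50000,12,23,OFF
50000,13,23,OFF
50000,18,23,OFF
50000,19,23,OFF
50000,20,23,OFF
50000,14,24,OFF
50000,15,24,OFF
50000,16,24,OFF
50000,17,24,OFF
60000,13,6,OFF
60000,14,6,OFF
60000,15,6,OFF
60000,16,6,OFF
60000,17,6,OFF
60000,18,6,OFF
60000,11,7,OFF
60000,12,7,OFF
60000,13,7,OFF
60000,18,7,OFF
60000,19,7,OFF
60000,20,7,OFF
60000,9,8,OFF
60000,10,8,OFF
60000,21,8,OFF
60000,22,8,OFF
60000,8,9,OFF
60000,9,9,OFF
60000,22,9,OFF
60000,23,9,OFF
60000,8,10,OFF
60000,23,10,OFF
60000,7,11,OFF
60000,24,11,OFF
60000,7,12,OFF
60000,24,12,OFF
60000,6,13,OFF
60000,7,13,OFF
60000,24,13,OFF
60000,25,13,OFF
60000,6,14,OFF
60000,25,14,OFF
60000,6,15,OFF
60000,25,15,OFF
60000,6,16,OFF
60000,25,16,OFF
60000,6,17,OFF
60000,25,17,OFF
60000,6,18,OFF
60000,7,18,OFF
60000,24,18,OFF
60000,25,18,OFF
60000,7,19,OFF
60000,24,19,OFF
60000,7,20,OFF
60000,24,20,OFF
60000,8,21,OFF
60000,23,21,OFF
60000,8,22,OFF
60000,9,22,OFF
60000,22,22,OFF
60000,23,22,OFF
60000,9,23,OFF
60000,10,23,OFF
60000,21,23,OFF
60000,22,23,OFF
60000,11,24,OFF
60000,12,24,OFF
60000,13,24,OFF
60000,18,24,OFF
60000,19,24,OFF
60000,20,24,OFF
60000,13,25,OFF
60000,14,25,OFF
60000,15,25,OFF
60000,16,25,OFF
60000,17,25,OFF
60000,18,25,OFF
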