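gw,trimester,percentile,reference,study
4,1,95,75,71.8
4,1,75,64,61.0
4,1,50,58,54.3
6,1,95,70,67.3
6,1,75,60,58.5
6,1,50,54,52.4
8,1,95,65,63.6
8,1,75,56,55.8
8,1,50,50,50.2
10,1,95,61,60.6
10,1,75,53,53.2
10,1,50,48,48.0
12,1,95,61,58.2
12,1,75,52,50.7
12,1,50,47,45.8
14,2,95,59,56.3
14,2,75,51,48.5
14,2,50,46,43.9
16,2,95,59,55.0
16,2,75,50,46.8
16,2,50,45,42.2
18,2,95,58,54.1
18,2,75,49,45.6
18,2,50,45,41.0
20,2,95,59,53.6
20,2,75,50,44.9
20,2,50,45,40.2
22,2,95,58,53.5
22,2,75,50,44.8
22,2,50,44,39.8
24,2,95,59,53.6
24,2,75,49,45.2
24,2,50,45,39.9
26,2,95,59,54.0
26,2,75,50,46.1
26,2,50,45,40.5
28,3,95,59,54.7
28,3,75,50,47.3
28,3,50,44,41.4
30,3,95,59,55.4
30,3,75,50,48.8
30,3,50,44,42.6
32,3,95,60,56.2
32,3,75,50,50.3
32,3,50,45,44.0
34,3,95,63,57.1
34,3,75,52,51.7
34,3,50,46,45.4
36,3,95,66,58.0
36,3,75,54,52.7
36,3,50,48,46.8
38,3,95,70,58.7
38,3,75,57,53.1
38,3,50,50,47.9
40,3,95,76,59.4
40,3,75,61,52.6
40,3,50,53,48.6
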