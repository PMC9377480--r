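age,sex,ex
21,female,61.3
22,female,60.3
23,female,59.4
24,female,58.4
25,female,57.5
26,female,56.5
27,female,55.6
28,female,54.6
29,female,53.7
30,female,52.7
31,female,51.7
32,female,50.8
33,female,49.8
34,female,48.9
35,female,47.9
36,female,47
37,female,46
38,female,45.1
39,female,44.1
40,female,43.1
41,female,42.2
42,female,41.2
43,female,40.3
44,female,39.3
45,female,38.4
46,female,37.4
47,female,36.5
48,female,35.5
49,female,34.6
50,female,33.6
51,female,32.6
52,female,31.7
53,female,30.7
54,female,29.8
55,female,28.8
56,female,27.9
57,female,26.9
58,female,26
59,female,25
60,female,24.3
61,female,23.6
62,female,22.8
63,female,22.1
64,female,21.4
65,female,20.7
66,female,19.9
67,female,19.2
68,female,18.5
69,female,17.8
70,female,17
71,female,16.3
72,female,15.6
73,female,14.9
74,female,14.1
75,female,13.4
76,female,12.7
77,female,12
78,female,11.2
79,female,10.5
80,female,9.8
21,male,56.6
22,male,55.7
23,male,54.8
24,male,53.9
25,male,52.9
26,male,52
27,male,51.1
28,male,50.2
29,male,49.3
30,male,48.4
31,male,47.4
32,male,46.5
33,male,45.6
34,male,44.7
35,male,43.8
36,male,42.9
37,male,41.9
38,male,41
39,male,40.1
40,male,39.2
41,male,38.3
42,male,37.4
43,male,36.5
44,male,35.5
45,male,34.6
46,male,33.7
47,male,32.8
48,male,31.9
49,male,31
50,male,30
51,male,29.1
52,male,28.2
53,male,27.3
54,male,26.4
55,male,25.5
56,male,24.5
57,male,23.6
58,male,22.7
59,male,21.8
60,male,21.1
61,male,20.4
62,male,19.7
63,male,19.1
64,male,18.4
65,male,17.7
66,male,17
67,male,16.3
68,male,15.6
69,male,14.9
70,male,14.3
71,male,13.6
72,male,12.9
73,male,12.2
74,male,11.5
75,male,10.8
76,male,10.1
77,male,9.5
78,male,8.8
79,male,8.1
80,male,7.4
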