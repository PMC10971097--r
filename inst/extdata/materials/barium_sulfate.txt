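# name: barium sulfate
# density: 4.5000
# composition: Ba 0.5884, S 0.1374, O 0.2742
# edges: 2.4720 5.2470 5.6240 5.9890 37.4410
# columns: energy_keV mass_attenuation_cm2_g
1.0000 1.701240e+04
1.5000 6.018629e+03
2.0000 2.877374e+03
2.4720 1.670582e+03
2.4720 2.002878e+03
2.5000 1.945254e+03
3.0000 1.213326e+03
3.5000 8.134372e+02
4.0000 5.758163e+02
4.5000 4.247334e+02
5.0000 3.237248e+02
5.2470 2.856697e+02
5.2470 5.534121e+02
5.5000 4.903121e+02
5.6240 4.630131e+02
5.6240 6.275168e+02
5.9890 5.341043e+02
5.9890 6.125780e+02
6.0000 6.093429e+02
6.5000 4.835474e+02
7.0000 3.904149e+02
7.5000 3.199517e+02
8.0000 2.656287e+02
8.5000 2.231112e+02
9.0000 1.892956e+02
9.5000 1.620532e+02
10.0000 1.398528e+02
10.5000 1.215966e+02
11.0000 1.064210e+02
11.5000 9.369904e+01
12.0000 8.295115e+01
12.5000 7.380652e+01
13.0000 6.597516e+01
13.5000 5.922807e+01
14.0000 5.338272e+01
14.5000 4.829241e+01
15.0000 4.383825e+01
15.5000 3.992542e+01
16.0000 3.647162e+01
16.5000 3.341101e+01
17.0000 3.068881e+01
17.5000 2.825919e+01
18.0000 2.608359e+01
18.5000 2.412944e+01
19.0000 2.236906e+01
19.5000 2.077883e+01
20.0000 1.933855e+01
20.5000 1.803541e+01
21.0000 1.684916e+01
21.5000 1.576687e+01
22.0000 1.477731e+01
22.5000 1.387067e+01
23.0000 1.303838e+01
23.5000 1.227289e+01
24.0000 1.156759e+01
24.5000 1.091662e+01
25.0000 1.031480e+01
25.5000 9.757545e+00
26.0000 9.240758e+00
26.5000 8.760802e+00
27.0000 8.314423e+00
27.5000 7.898708e+00
28.0000 7.511045e+00
28.5000 7.149084e+00
29.0000 6.810709e+00
29.5000 6.494012e+00
30.0000 6.197268e+00
30.5000 5.921367e+00
31.0000 5.662229e+00
31.5000 5.418586e+00
32.0000 5.189281e+00
32.5000 4.973265e+00
33.0000 4.769576e+00
33.5000 4.577336e+00
34.0000 4.395744e+00
34.5000 4.224061e+00
35.0000 4.061614e+00
35.5000 3.907781e+00
36.0000 3.761993e+00
36.5000 3.623721e+00
37.0000 3.492484e+00
37.4410 3.382212e+00
37.4410 1.736697e+01
37.5000 1.728230e+01
38.0000 1.658636e+01
38.5000 1.592723e+01
39.0000 1.530252e+01
39.5000 1.471001e+01
40.0000 1.414767e+01
40.5000 1.361435e+01
41.0000 1.310752e+01
41.5000 1.262557e+01
42.0000 1.216700e+01
42.5000 1.173041e+01
43.0000 1.131451e+01
43.5000 1.091808e+01
44.0000 1.054002e+01
44.5000 1.017927e+01
45.0000 9.834851e+00
45.5000 9.505862e+00
46.0000 9.191448e+00
46.5000 8.890816e+00
47.0000 8.603219e+00
47.5000 8.327963e+00
48.0000 8.064396e+00
48.5000 7.811905e+00
49.0000 7.569917e+00
49.5000 7.337893e+00
50.0000 7.115328e+00
50.5000 6.902187e+00
51.0000 6.697563e+00
51.5000 6.501037e+00
52.0000 6.312213e+00
52.5000 6.130719e+00
53.0000 5.956204e+00
53.5000 5.788336e+00
54.0000 5.626803e+00
54.5000 5.471310e+00
55.0000 5.321579e+00
55.5000 5.177344e+00
56.0000 5.038358e+00
56.5000 4.915433e+00
57.0000 4.801749e+00
57.5000 4.691715e+00
58.0000 4.585183e+00
58.5000 4.482013e+00
59.0000 4.382070e+00
59.5000 4.285228e+00
60.0000 4.191366e+00
60.5000 4.100625e+00
61.0000 4.012630e+00
61.5000 3.927275e+00
62.0000 3.844460e+00
62.5000 3.764090e+00
63.0000 3.686074e+00
63.5000 3.610325e+00
64.0000 3.536760e+00
64.5000 3.465299e+00
65.0000 3.395865e+00
65.5000 3.328388e+00
66.0000 3.262796e+00
66.5000 3.199023e+00
67.0000 3.137006e+00
67.5000 3.076683e+00
68.0000 3.017997e+00
68.5000 2.960890e+00
69.0000 2.905309e+00
69.5000 2.851203e+00
70.0000 2.798521e+00
70.5000 2.747218e+00
71.0000 2.697246e+00
71.5000 2.648563e+00
72.0000 2.601126e+00
72.5000 2.554894e+00
73.0000 2.509830e+00
73.5000 2.465896e+00
74.0000 2.423056e+00
74.5000 2.381275e+00
75.0000 2.340520e+00
75.5000 2.300760e+00
76.0000 2.261964e+00
76.5000 2.224102e+00
77.0000 2.187145e+00
77.5000 2.151066e+00
78.0000 2.115839e+00
78.5000 2.081439e+00
79.0000 2.047840e+00
79.5000 2.015019e+00
80.0000 1.982953e+00
80.5000 1.951740e+00
81.0000 1.921236e+00
81.5000 1.891420e+00
82.0000 1.862274e+00
82.5000 1.833779e+00
83.0000 1.805915e+00
83.5000 1.778665e+00
84.0000 1.752012e+00
84.5000 1.725939e+00
85.0000 1.700430e+00
85.5000 1.675470e+00
86.0000 1.651044e+00
86.5000 1.627137e+00
87.0000 1.603735e+00
87.5000 1.580825e+00
88.0000 1.558393e+00
88.5000 1.536428e+00
89.0000 1.514916e+00
89.5000 1.493845e+00
90.0000 1.473205e+00
90.5000 1.452983e+00
91.0000 1.433170e+00
91.5000 1.413754e+00
92.0000 1.394726e+00
92.5000 1.376076e+00
93.0000 1.357794e+00
93.5000 1.339871e+00
94.0000 1.322297e+00
94.5000 1.305065e+00
95.0000 1.288166e+00
95.5000 1.271592e+00
96.0000 1.255334e+00
96.5000 1.239385e+00
97.0000 1.223738e+00
97.5000 1.208385e+00
98.0000 1.193319e+00
98.5000 1.178534e+00
99.0000 1.164022e+00
99.5000 1.149778e+00
100.0000 1.135794e+00
100.5000 1.122134e+00
101.0000 1.108721e+00
101.5000 1.095551e+00
102.0000 1.082617e+00
102.5000 1.069915e+00
103.0000 1.057439e+00
103.5000 1.045184e+00
104.0000 1.033144e+00
104.5000 1.021316e+00
105.0000 1.009694e+00
105.5000 9.982732e-01
106.0000 9.870501e-01
106.5000 9.760199e-01
107.0000 9.651784e-01
107.5000 9.545214e-01
108.0000 9.440450e-01
108.5000 9.337452e-01
109.0000 9.236182e-01
109.5000 9.136604e-01
110.0000 9.038681e-01
110.5000 8.942378e-01
111.0000 8.847661e-01
111.5000 8.754496e-01
112.0000 8.662851e-01
112.5000 8.572694e-01
113.0000 8.483995e-01
113.5000 8.396723e-01
114.0000 8.310848e-01
114.5000 8.226343e-01
115.0000 8.143179e-01
115.5000 8.061329e-01
116.0000 7.980766e-01
116.5000 7.901465e-01
117.0000 7.823400e-01
117.5000 7.746547e-01
118.0000 7.670881e-01
118.5000 7.596378e-01
119.0000 7.523017e-01
119.5000 7.450775e-01
120.0000 7.379629e-01
120.5000 7.309559e-01
121.0000 7.240543e-01
121.5000 7.172561e-01
122.0000 7.105594e-01
122.5000 7.039621e-01
123.0000 6.974625e-01
123.5000 6.910586e-01
124.0000 6.847486e-01
124.5000 6.785308e-01
125.0000 6.724035e-01
125.5000 6.663648e-01
126.0000 6.604133e-01
126.5000 6.545473e-01
127.0000 6.487652e-01
127.5000 6.430654e-01
128.0000 6.374465e-01
128.5000 6.319070e-01
129.0000 6.264454e-01
129.5000 6.210603e-01
130.0000 6.157504e-01
130.5000 6.105143e-01
131.0000 6.053507e-01
131.5000 6.002583e-01
132.0000 5.952358e-01
132.5000 5.902820e-01
133.0000 5.853957e-01
133.5000 5.805757e-01
134.0000 5.758208e-01
134.5000 5.711300e-01
135.0000 5.665020e-01
135.5000 5.619358e-01
136.0000 5.574304e-01
136.5000 5.529848e-01
137.0000 5.485977e-01
137.5000 5.442684e-01
138.0000 5.399958e-01
138.5000 5.357790e-01
139.0000 5.316169e-01
139.5000 5.275088e-01
140.0000 5.234536e-01
140.5000 5.194505e-01
141.0000 5.154987e-01
141.5000 5.115973e-01
142.0000 5.077455e-01
142.5000 5.039424e-01
143.0000 5.001873e-01
143.5000 4.964794e-01
144.0000 4.928178e-01
144.5000 4.892020e-01
145.0000 4.856310e-01
145.5000 4.821043e-01
146.0000 4.786210e-01
146.5000 4.751806e-01
147.0000 4.717822e-01
147.5000 4.684253e-01
148.0000 4.651093e-01
148.5000 4.618333e-01
149.0000 4.585969e-01
149.5000 4.553994e-01
150.0000 4.522402e-01
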