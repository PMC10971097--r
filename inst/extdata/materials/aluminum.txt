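# name: aluminum
# density: 2.6990
# composition: Al 1.0
# edges: 1.5598
# columns: energy_keV mass_attenuation_cm2_g
1.0000 1.185000e+03
1.5000 4.022000e+02
1.5598 3.621006e+02
1.5598 3.956994e+03
2.0000 2.263000e+03
2.5000 1.266315e+03
3.0000 7.880000e+02
3.5000 5.182565e+02
4.0000 3.605000e+02
4.5000 2.595093e+02
5.0000 1.934000e+02
5.5000 1.475811e+02
6.0000 1.153000e+02
6.5000 9.155134e+01
7.0000 7.394805e+01
7.5000 6.061635e+01
8.0000 5.033000e+01
8.5000 4.216309e+01
9.0000 3.568079e+01
9.5000 3.046893e+01
10.0000 2.623000e+01
10.5000 2.272206e+01
11.0000 1.981518e+01
11.5000 1.738568e+01
12.0000 1.533922e+01
12.5000 1.360302e+01
13.0000 1.212031e+01
13.5000 1.084636e+01
14.0000 9.745600e+00
14.5000 8.789500e+00
15.0000 7.955000e+00
15.5000 7.230307e+00
16.0000 6.591595e+00
16.5000 6.026433e+00
17.0000 5.524493e+00
17.5000 5.077143e+00
18.0000 4.677131e+00
18.5000 4.318334e+00
19.0000 3.995558e+00
19.5000 3.704376e+00
20.0000 3.441000e+00
20.5000 3.215041e+00
21.0000 3.008840e+00
21.5000 2.820260e+00
22.0000 2.647436e+00
22.5000 2.488737e+00
23.0000 2.342732e+00
23.5000 2.208162e+00
24.0000 2.083916e+00
24.5000 1.969011e+00
25.0000 1.862574e+00
25.5000 1.763831e+00
26.0000 1.672091e+00
26.5000 1.586735e+00
27.0000 1.507213e+00
27.5000 1.433027e+00
28.0000 1.363732e+00
28.5000 1.298928e+00
29.0000 1.238250e+00
29.5000 1.181373e+00
30.0000 1.128000e+00
30.5000 1.084454e+00
31.0000 1.043257e+00
31.5000 1.004247e+00
32.0000 9.672759e-01
32.5000 9.322080e-01
33.0000 8.989182e-01
33.5000 8.672912e-01
34.0000 8.372212e-01
34.5000 8.086102e-01
35.0000 7.813677e-01
35.5000 7.554103e-01
36.0000 7.306603e-01
36.5000 7.070460e-01
37.0000 6.845008e-01
37.5000 6.629628e-01
38.0000 6.423745e-01
38.5000 6.226823e-01
39.0000 6.038363e-01
39.5000 5.857900e-01
40.0000 5.685000e-01
40.5000 5.549091e-01
41.0000 5.418039e-01
41.5000 5.291616e-01
42.0000 5.169603e-01
42.5000 5.051799e-01
43.0000 4.938010e-01
43.5000 4.828056e-01
44.0000 4.721765e-01
44.5000 4.618976e-01
45.0000 4.519536e-01
45.5000 4.423300e-01
46.0000 4.330132e-01
46.5000 4.239902e-01
47.0000 4.152487e-01
47.5000 4.067771e-01
48.0000 3.985644e-01
48.5000 3.906000e-01
49.0000 3.828741e-01
49.5000 3.753771e-01
50.0000 3.681000e-01
50.5000 3.624890e-01
51.0000 3.570176e-01
51.5000 3.516809e-01
52.0000 3.464744e-01
52.5000 3.413937e-01
53.0000 3.364346e-01
53.5000 3.315931e-01
54.0000 3.268654e-01
54.5000 3.222477e-01
55.0000 3.177365e-01
55.5000 3.133285e-01
56.0000 3.090203e-01
56.5000 3.048089e-01
57.0000 3.006912e-01
57.5000 2.966644e-01
58.0000 2.927257e-01
58.5000 2.888724e-01
59.0000 2.851020e-01
59.5000 2.814120e-01
60.0000 2.778000e-01
60.5000 2.752504e-01
61.0000 2.727449e-01
61.5000 2.702823e-01
62.0000 2.678617e-01
62.5000 2.654819e-01
63.0000 2.631420e-01
63.5000 2.608410e-01
64.0000 2.585779e-01
64.5000 2.563518e-01
65.0000 2.541619e-01
65.5000 2.520072e-01
66.0000 2.498870e-01
66.5000 2.478004e-01
67.0000 2.457466e-01
67.5000 2.437250e-01
68.0000 2.417347e-01
68.5000 2.397751e-01
69.0000 2.378455e-01
69.5000 2.359451e-01
70.0000 2.340734e-01
70.5000 2.322297e-01
71.0000 2.304135e-01
71.5000 2.286240e-01
72.0000 2.268607e-01
72.5000 2.251231e-01
73.0000 2.234106e-01
73.5000 2.217227e-01
74.0000 2.200588e-01
74.5000 2.184186e-01
75.0000 2.168014e-01
75.5000 2.152068e-01
76.0000 2.136343e-01
76.5000 2.120835e-01
77.0000 2.105540e-01
77.5000 2.090453e-01
78.0000 2.075570e-01
78.5000 2.060887e-01
79.0000 2.046400e-01
79.5000 2.032106e-01
80.0000 2.018000e-01
80.5000 2.008493e-01
81.0000 1.999089e-01
81.5000 1.989786e-01
82.0000 1.980584e-01
82.5000 1.971479e-01
83.0000 1.962471e-01
83.5000 1.953558e-01
84.0000 1.944738e-01
84.5000 1.936010e-01
85.0000 1.927372e-01
85.5000 1.918823e-01
86.0000 1.910362e-01
86.5000 1.901986e-01
87.0000 1.893695e-01
87.5000 1.885488e-01
88.0000 1.877363e-01
88.5000 1.869318e-01
89.0000 1.861353e-01
89.5000 1.853466e-01
90.0000 1.845656e-01
90.5000 1.837922e-01
91.0000 1.830263e-01
91.5000 1.822678e-01
92.0000 1.815165e-01
92.5000 1.807723e-01
93.0000 1.800352e-01
93.5000 1.793050e-01
94.0000 1.785817e-01
94.5000 1.778651e-01
95.0000 1.771551e-01
95.5000 1.764517e-01
96.0000 1.757547e-01
96.5000 1.750640e-01
97.0000 1.743796e-01
97.5000 1.737014e-01
98.0000 1.730293e-01
98.5000 1.723632e-01
99.0000 1.717030e-01
99.5000 1.710486e-01
100.0000 1.704000e-01
100.5000 1.699555e-01
101.0000 1.695143e-01
101.5000 1.690765e-01
102.0000 1.686419e-01
102.5000 1.682106e-01
103.0000 1.677825e-01
103.5000 1.673575e-01
104.0000 1.669357e-01
104.5000 1.665169e-01
105.0000 1.661011e-01
105.5000 1.656884e-01
106.0000 1.652786e-01
106.5000 1.648718e-01
107.0000 1.644679e-01
107.5000 1.640668e-01
108.0000 1.636686e-01
108.5000 1.632731e-01
109.0000 1.628805e-01
109.5000 1.624905e-01
110.0000 1.621033e-01
110.5000 1.617188e-01
111.0000 1.613369e-01
111.5000 1.609576e-01
112.0000 1.605808e-01
112.5000 1.602067e-01
113.0000 1.598350e-01
113.5000 1.594659e-01
114.0000 1.590992e-01
114.5000 1.587350e-01
115.0000 1.583732e-01
115.5000 1.580138e-01
116.0000 1.576567e-01
116.5000 1.573020e-01
117.0000 1.569496e-01
117.5000 1.565994e-01
118.0000 1.562516e-01
118.5000 1.559060e-01
119.0000 1.555626e-01
119.5000 1.552213e-01
120.0000 1.548823e-01
120.5000 1.545454e-01
121.0000 1.542106e-01
121.5000 1.538779e-01
122.0000 1.535473e-01
122.5000 1.532188e-01
123.0000 1.528923e-01
123.5000 1.525678e-01
124.0000 1.522453e-01
124.5000 1.519248e-01
125.0000 1.516062e-01
125.5000 1.512896e-01
126.0000 1.509749e-01
126.5000 1.506621e-01
127.0000 1.503512e-01
127.5000 1.500421e-01
128.0000 1.497348e-01
128.5000 1.494294e-01
129.0000 1.491258e-01
129.5000 1.488240e-01
130.0000 1.485240e-01
130.5000 1.482257e-01
131.0000 1.479291e-01
131.5000 1.476343e-01
132.0000 1.473412e-01
132.5000 1.470497e-01
133.0000 1.467599e-01
133.5000 1.464718e-01
134.0000 1.461853e-01
134.5000 1.459005e-01
135.0000 1.456172e-01
135.5000 1.453356e-01
136.0000 1.450555e-01
136.5000 1.447770e-01
137.0000 1.445000e-01
137.5000 1.442246e-01
138.0000 1.439507e-01
138.5000 1.436783e-01
139.0000 1.434074e-01
139.5000 1.431380e-01
140.0000 1.428700e-01
140.5000 1.426036e-01
141.0000 1.423385e-01
141.5000 1.420749e-01
142.0000 1.418127e-01
142.5000 1.415518e-01
143.0000 1.412924e-01
143.5000 1.410344e-01
144.0000 1.407777e-01
144.5000 1.405224e-01
145.0000 1.402684e-01
145.5000 1.400158e-01
146.0000 1.397644e-01
146.5000 1.395144e-01
147.0000 1.392657e-01
147.5000 1.390183e-01
148.0000 1.387721e-01
148.5000 1.385272e-01
149.0000 1.382836e-01
149.5000 1.380412e-01
150.0000 1.378000e-01
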