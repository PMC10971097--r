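# name: iodine
# density: 4.9300
# composition: I 1.0
# edges: 4.5570 4.8520 5.1880 33.1690
# columns: energy_keV mass_attenuation_cm2_g
1.0000 2.367500e+04
1.5000 8.427950e+03
2.0000 4.053788e+03
2.5000 2.300050e+03
3.0000 1.448973e+03
3.5000 9.812536e+02
4.0000 7.006386e+02
4.5000 5.209082e+02
4.5570 5.046865e+02
4.5570 1.098391e+03
4.8520 9.370714e+02
4.8520 1.308097e+03
5.0000 1.212106e+03
5.1880 1.103797e+03
5.1880 1.278959e+03
5.5000 1.080688e+03
6.0000 8.409548e+02
6.5000 6.678010e+02
7.0000 5.395288e+02
7.5000 4.424231e+02
8.0000 3.675192e+02
8.5000 3.087859e+02
9.0000 2.620618e+02
9.5000 2.244111e+02
10.0000 1.937219e+02
10.5000 1.684477e+02
11.0000 1.474378e+02
11.5000 1.298242e+02
12.0000 1.149434e+02
12.5000 1.022819e+02
13.0000 9.143833e+01
13.5000 8.209581e+01
14.0000 7.400163e+01
14.5000 6.695271e+01
15.0000 6.078452e+01
15.5000 5.536276e+01
16.0000 5.057710e+01
16.5000 4.633629e+01
17.0000 4.256441e+01
17.5000 3.919794e+01
18.0000 3.618347e+01
18.5000 3.347582e+01
19.0000 3.103667e+01
19.5000 2.883328e+01
20.0000 2.683765e+01
20.5000 2.502567e+01
21.0000 2.337652e+01
21.5000 2.187219e+01
22.0000 2.049700e+01
22.5000 1.923726e+01
23.0000 1.808103e+01
23.5000 1.701780e+01
24.0000 1.603833e+01
24.5000 1.513446e+01
25.0000 1.429898e+01
25.5000 1.352549e+01
26.0000 1.280829e+01
26.5000 1.214231e+01
27.0000 1.152302e+01
27.5000 1.094636e+01
28.0000 1.040870e+01
28.5000 9.906760e+00
29.0000 9.437600e+00
29.5000 8.998561e+00
30.0000 8.587243e+00
30.5000 8.201470e+00
31.0000 7.839272e+00
31.5000 7.498858e+00
32.0000 7.178599e+00
32.5000 6.877010e+00
33.0000 6.592737e+00
33.1690 6.500348e+00
33.1690 3.575034e+01
33.5000 3.465971e+01
34.0000 3.309438e+01
34.5000 3.162148e+01
35.0000 3.023432e+01
35.5000 2.892678e+01
36.0000 2.769327e+01
36.5000 2.652865e+01
37.0000 2.542820e+01
37.5000 2.438759e+01
38.0000 2.340282e+01
38.5000 2.247022e+01
39.0000 2.158639e+01
39.5000 2.074822e+01
40.0000 1.995280e+01
40.5000 1.919745e+01
41.0000 1.847970e+01
41.5000 1.779725e+01
42.0000 1.714797e+01
42.5000 1.652987e+01
43.0000 1.594112e+01
43.5000 1.538000e+01
44.0000 1.484492e+01
44.5000 1.433439e+01
45.0000 1.384704e+01
45.5000 1.338156e+01
46.0000 1.293674e+01
46.5000 1.251147e+01
47.0000 1.210468e+01
47.5000 1.171538e+01
48.0000 1.134266e+01
48.5000 1.098563e+01
49.0000 1.064349e+01
49.5000 1.031547e+01
50.0000 1.001993e+01
50.5000 9.754773e+00
51.0000 9.499242e+00
51.5000 9.252896e+00
52.0000 9.015322e+00
52.5000 8.786125e+00
53.0000 8.564935e+00
53.5000 8.351400e+00
54.0000 8.145187e+00
54.5000 7.945980e+00
55.0000 7.753480e+00
55.5000 7.567402e+00
56.0000 7.387477e+00
56.5000 7.213450e+00
57.0000 7.045076e+00
57.5000 6.882125e+00
58.0000 6.724377e+00
58.5000 6.571623e+00
59.0000 6.423663e+00
59.5000 6.280308e+00
60.0000 6.141379e+00
60.5000 6.006702e+00
61.0000 5.876114e+00
61.5000 5.749458e+00
62.0000 5.626585e+00
62.5000 5.507354e+00
63.0000 5.391627e+00
63.5000 5.279276e+00
64.0000 5.170176e+00
64.5000 5.064208e+00
65.0000 4.961259e+00
65.5000 4.861221e+00
66.0000 4.763990e+00
66.5000 4.669467e+00
67.0000 4.577556e+00
67.5000 4.488167e+00
68.0000 4.401212e+00
68.5000 4.316607e+00
69.0000 4.234273e+00
69.5000 4.154133e+00
70.0000 4.076113e+00
70.5000 4.000142e+00
71.0000 3.926152e+00
71.5000 3.854078e+00
72.0000 3.783857e+00
72.5000 3.715430e+00
73.0000 3.648738e+00
73.5000 3.583726e+00
74.0000 3.520340e+00
74.5000 3.458529e+00
75.0000 3.398244e+00
75.5000 3.339437e+00
76.0000 3.282063e+00
76.5000 3.226076e+00
77.0000 3.171436e+00
77.5000 3.118100e+00
78.0000 3.066030e+00
78.5000 3.015187e+00
79.0000 2.965535e+00
79.5000 2.917039e+00
80.0000 2.869665e+00
80.5000 2.823380e+00
81.0000 2.778152e+00
81.5000 2.733951e+00
82.0000 2.690747e+00
82.5000 2.648512e+00
83.0000 2.607219e+00
83.5000 2.566840e+00
84.0000 2.527350e+00
84.5000 2.488725e+00
85.0000 2.450940e+00
85.5000 2.413972e+00
86.0000 2.377800e+00
86.5000 2.342401e+00
87.0000 2.307754e+00
87.5000 2.273839e+00
88.0000 2.240637e+00
88.5000 2.208129e+00
89.0000 2.176295e+00
89.5000 2.145120e+00
90.0000 2.114584e+00
90.5000 2.084672e+00
91.0000 2.055368e+00
91.5000 2.026656e+00
92.0000 1.998520e+00
92.5000 1.970946e+00
93.0000 1.943921e+00
93.5000 1.917429e+00
94.0000 1.891458e+00
94.5000 1.865995e+00
95.0000 1.841026e+00
95.5000 1.816541e+00
96.0000 1.792527e+00
96.5000 1.768972e+00
97.0000 1.745866e+00
97.5000 1.723197e+00
98.0000 1.700956e+00
98.5000 1.679131e+00
99.0000 1.657713e+00
99.5000 1.636693e+00
100.0000 1.616060e+00
100.5000 1.595807e+00
101.0000 1.575923e+00
101.5000 1.556401e+00
102.0000 1.537233e+00
102.5000 1.518409e+00
103.0000 1.499922e+00
103.5000 1.481765e+00
104.0000 1.463930e+00
104.5000 1.446410e+00
105.0000 1.429197e+00
105.5000 1.412285e+00
106.0000 1.395668e+00
106.5000 1.379338e+00
107.0000 1.363289e+00
107.5000 1.347516e+00
108.0000 1.332012e+00
108.5000 1.316771e+00
109.0000 1.301788e+00
109.5000 1.287056e+00
110.0000 1.272572e+00
110.5000 1.258329e+00
111.0000 1.244323e+00
111.5000 1.230547e+00
112.0000 1.216999e+00
112.5000 1.203672e+00
113.0000 1.190562e+00
113.5000 1.177665e+00
114.0000 1.164976e+00
114.5000 1.152491e+00
115.0000 1.140206e+00
115.5000 1.128117e+00
116.0000 1.116220e+00
116.5000 1.104510e+00
117.0000 1.092984e+00
117.5000 1.081639e+00
118.0000 1.070471e+00
118.5000 1.059476e+00
119.0000 1.048651e+00
119.5000 1.037992e+00
120.0000 1.027497e+00
120.5000 1.017162e+00
121.0000 1.006984e+00
121.5000 9.969596e-01
122.0000 9.870863e-01
122.5000 9.773611e-01
123.0000 9.677812e-01
123.5000 9.583438e-01
124.0000 9.490461e-01
124.5000 9.398856e-01
125.0000 9.308596e-01
125.5000 9.219656e-01
126.0000 9.132013e-01
126.5000 9.045640e-01
127.0000 8.960516e-01
127.5000 8.876617e-01
128.0000 8.793921e-01
128.5000 8.712405e-01
129.0000 8.632048e-01
129.5000 8.552829e-01
130.0000 8.474727e-01
130.5000 8.397723e-01
131.0000 8.321796e-01
131.5000 8.246927e-01
132.0000 8.173098e-01
132.5000 8.100290e-01
133.0000 8.028485e-01
133.5000 7.957665e-01
134.0000 7.887813e-01
134.5000 7.818912e-01
135.0000 7.750946e-01
135.5000 7.683898e-01
136.0000 7.617753e-01
136.5000 7.552495e-01
137.0000 7.488108e-01
137.5000 7.424578e-01
138.0000 7.361890e-01
138.5000 7.300030e-01
139.0000 7.238984e-01
139.5000 7.178738e-01
140.0000 7.119280e-01
140.5000 7.060594e-01
141.0000 7.002670e-01
141.5000 6.945493e-01
142.0000 6.889052e-01
142.5000 6.833335e-01
143.0000 6.778330e-01
143.5000 6.724024e-01
144.0000 6.670408e-01
144.5000 6.617468e-01
145.0000 6.565196e-01
145.5000 6.513578e-01
146.0000 6.462607e-01
146.5000 6.412269e-01
147.0000 6.362557e-01
147.5000 6.313459e-01
148.0000 6.264966e-01
148.5000 6.217069e-01
149.0000 6.169758e-01
149.5000 6.123023e-01
150.0000 6.076857e-01
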