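# name: cortical bone (ICRU-44)
# density: 1.9200
# composition: H 0.034, C 0.155, N 0.042, O 0.435, Na 0.001, Mg 0.002, P 0.103, S 0.003, Ca 0.225
# edges: 1.0721 1.3050 2.1455 2.4720 4.0380
# columns: energy_keV mass_attenuation_cm2_g
1.0000 4.331477e+03
1.0721 3.592028e+03
1.0721 3.599920e+03
1.3050 2.122139e+03
1.3050 2.135405e+03
1.5000 1.468460e+03
2.0000 6.506073e+02
2.1455 5.329295e+02
2.1455 8.481077e+02
2.4720 5.632570e+02
2.4720 5.705126e+02
2.5000 5.522600e+02
3.0000 3.262634e+02
3.5000 2.099766e+02
4.0000 1.433597e+02
4.0380 1.395135e+02
4.0380 3.971382e+02
4.5000 2.876114e+02
5.0000 2.101573e+02
5.5000 1.601723e+02
6.0000 1.250017e+02
6.5000 9.918497e+01
7.0000 8.006440e+01
7.5000 6.559418e+01
8.0000 5.443674e+01
8.5000 4.565421e+01
9.0000 3.867616e+01
9.5000 3.306029e+01
10.0000 2.848859e+01
10.5000 2.484493e+01
11.0000 2.180605e+01
11.5000 1.925050e+01
12.0000 1.708512e+01
12.5000 1.523760e+01
13.0000 1.365121e+01
13.5000 1.228103e+01
14.0000 1.109112e+01
14.5000 1.005254e+01
15.0000 9.141770e+00
15.5000 8.319142e+00
16.0000 7.593471e+00
16.5000 6.950804e+00
17.0000 6.379538e+00
17.5000 5.869969e+00
18.0000 5.413941e+00
18.5000 5.004561e+00
19.0000 4.635979e+00
19.5000 4.303206e+00
20.0000 4.001972e+00
20.5000 3.739980e+00
21.0000 3.501104e+00
21.5000 3.282816e+00
22.0000 3.082915e+00
22.5000 2.899478e+00
23.0000 2.730822e+00
23.5000 2.575467e+00
24.0000 2.432107e+00
24.5000 2.299590e+00
25.0000 2.176896e+00
25.5000 2.063117e+00
26.0000 1.957446e+00
26.5000 1.859162e+00
27.0000 1.767621e+00
27.5000 1.682246e+00
28.0000 1.602517e+00
28.5000 1.527968e+00
29.0000 1.458179e+00
29.5000 1.392768e+00
30.0000 1.331394e+00
30.5000 1.278129e+00
31.0000 1.227943e+00
31.5000 1.180609e+00
32.0000 1.135922e+00
32.5000 1.093693e+00
33.0000 1.053751e+00
33.5000 1.015938e+00
34.0000 9.801107e-01
34.5000 9.461352e-01
35.0000 9.138899e-01
35.5000 8.832625e-01
36.0000 8.541494e-01
36.5000 8.264551e-01
37.0000 8.000913e-01
37.5000 7.749763e-01
38.0000 7.510344e-01
38.5000 7.281955e-01
39.0000 7.063946e-01
39.5000 6.855712e-01
40.0000 6.656692e-01
40.5000 6.485781e-01
41.0000 6.321913e-01
41.5000 6.164712e-01
42.0000 6.013823e-01
42.5000 5.868918e-01
43.0000 5.729687e-01
43.5000 5.595840e-01
44.0000 5.467105e-01
44.5000 5.343229e-01
45.0000 5.223971e-01
45.5000 5.109106e-01
46.0000 4.998422e-01
46.5000 4.891721e-01
47.0000 4.788814e-01
47.5000 4.689525e-01
48.0000 4.593686e-01
48.5000 4.501141e-01
49.0000 4.411741e-01
49.5000 4.325344e-01
50.0000 4.241819e-01
50.5000 4.170639e-01
51.0000 4.101636e-01
51.5000 4.034723e-01
52.0000 3.969814e-01
52.5000 3.906829e-01
53.0000 3.845691e-01
53.5000 3.786329e-01
54.0000 3.728672e-01
54.5000 3.672655e-01
55.0000 3.618215e-01
55.5000 3.565293e-01
56.0000 3.513831e-01
56.5000 3.463776e-01
57.0000 3.415076e-01
57.5000 3.367680e-01
58.0000 3.321543e-01
58.5000 3.276619e-01
59.0000 3.232864e-01
59.5000 3.190238e-01
60.0000 3.148702e-01
60.5000 3.115279e-01
61.0000 3.082610e-01
61.5000 3.050669e-01
62.0000 3.019435e-01
62.5000 2.988885e-01
63.0000 2.959000e-01
63.5000 2.929758e-01
64.0000 2.901140e-01
64.5000 2.873128e-01
65.0000 2.845705e-01
65.5000 2.818852e-01
66.0000 2.792552e-01
66.5000 2.766791e-01
67.0000 2.741553e-01
67.5000 2.716822e-01
68.0000 2.692585e-01
68.5000 2.668828e-01
69.0000 2.645537e-01
69.5000 2.622700e-01
70.0000 2.600303e-01
70.5000 2.578336e-01
71.0000 2.556787e-01
71.5000 2.535644e-01
72.0000 2.514896e-01
72.5000 2.494534e-01
73.0000 2.474547e-01
73.5000 2.454925e-01
74.0000 2.435659e-01
74.5000 2.416740e-01
75.0000 2.398160e-01
75.5000 2.379908e-01
76.0000 2.361978e-01
76.5000 2.344362e-01
77.0000 2.327050e-01
77.5000 2.310037e-01
78.0000 2.293314e-01
78.5000 2.276876e-01
79.0000 2.260714e-01
79.5000 2.244822e-01
80.0000 2.229194e-01
80.5000 2.217193e-01
81.0000 2.205361e-01
81.5000 2.193693e-01
82.0000 2.182187e-01
82.5000 2.170839e-01
83.0000 2.159646e-01
83.5000 2.148604e-01
84.0000 2.137711e-01
84.5000 2.126964e-01
85.0000 2.116360e-01
85.5000 2.105896e-01
86.0000 2.095569e-01
86.5000 2.085377e-01
87.0000 2.075317e-01
87.5000 2.065386e-01
88.0000 2.055582e-01
88.5000 2.045903e-01
89.0000 2.036346e-01
89.5000 2.026909e-01
90.0000 2.017590e-01
90.5000 2.008386e-01
91.0000 1.999295e-01
91.5000 1.990316e-01
92.0000 1.981446e-01
92.5000 1.972683e-01
93.0000 1.964026e-01
93.5000 1.955472e-01
94.0000 1.947019e-01
94.5000 1.938667e-01
95.0000 1.930412e-01
95.5000 1.922254e-01
96.0000 1.914190e-01
96.5000 1.906219e-01
97.0000 1.898340e-01
97.5000 1.890551e-01
98.0000 1.882850e-01
98.5000 1.875235e-01
99.0000 1.867706e-01
99.5000 1.860261e-01
100.0000 1.852898e-01
100.5000 1.847557e-01
101.0000 1.842264e-01
101.5000 1.837017e-01
102.0000 1.831815e-01
102.5000 1.826659e-01
103.0000 1.821547e-01
103.5000 1.816479e-01
104.0000 1.811455e-01
104.5000 1.806472e-01
105.0000 1.801532e-01
105.5000 1.796634e-01
106.0000 1.791777e-01
106.5000 1.786959e-01
107.0000 1.782182e-01
107.5000 1.777444e-01
108.0000 1.772746e-01
108.5000 1.768085e-01
109.0000 1.763462e-01
109.5000 1.758877e-01
110.0000 1.754328e-01
110.5000 1.749816e-01
111.0000 1.745340e-01
111.5000 1.740899e-01
112.0000 1.736493e-01
112.5000 1.732122e-01
113.0000 1.727785e-01
113.5000 1.723482e-01
114.0000 1.719211e-01
114.5000 1.714974e-01
115.0000 1.710770e-01
115.5000 1.706597e-01
116.0000 1.702456e-01
116.5000 1.698347e-01
117.0000 1.694268e-01
117.5000 1.690220e-01
118.0000 1.686202e-01
118.5000 1.682214e-01
119.0000 1.678256e-01
119.5000 1.674327e-01
120.0000 1.670426e-01
120.5000 1.666554e-01
121.0000 1.662710e-01
121.5000 1.658894e-01
122.0000 1.655105e-01
122.5000 1.651343e-01
123.0000 1.647608e-01
123.5000 1.643900e-01
124.0000 1.640218e-01
124.5000 1.636562e-01
125.0000 1.632932e-01
125.5000 1.629327e-01
126.0000 1.625747e-01
126.5000 1.622192e-01
127.0000 1.618661e-01
127.5000 1.615155e-01
128.0000 1.611672e-01
128.5000 1.608213e-01
129.0000 1.604778e-01
129.5000 1.601366e-01
130.0000 1.597977e-01
130.5000 1.594611e-01
131.0000 1.591267e-01
131.5000 1.587945e-01
132.0000 1.584645e-01
132.5000 1.581367e-01
133.0000 1.578111e-01
133.5000 1.574875e-01
134.0000 1.571661e-01
134.5000 1.568468e-01
135.0000 1.565295e-01
135.5000 1.562143e-01
136.0000 1.559011e-01
136.5000 1.555899e-01
137.0000 1.552807e-01
137.5000 1.549734e-01
138.0000 1.546681e-01
138.5000 1.543647e-01
139.0000 1.540632e-01
139.5000 1.537636e-01
140.0000 1.534658e-01
140.5000 1.531699e-01
141.0000 1.528758e-01
141.5000 1.525835e-01
142.0000 1.522930e-01
142.5000 1.520043e-01
143.0000 1.517173e-01
143.5000 1.514321e-01
144.0000 1.511485e-01
144.5000 1.508667e-01
145.0000 1.505866e-01
145.5000 1.503081e-01
146.0000 1.500313e-01
146.5000 1.497562e-01
147.0000 1.494826e-01
147.5000 1.492107e-01
148.0000 1.489403e-01
148.5000 1.486716e-01
149.0000 1.484044e-01
149.5000 1.481387e-01
150.0000 1.478746e-01
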