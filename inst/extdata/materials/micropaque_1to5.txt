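# name: Micropaque 1:5 (0.2 g/mL BaSO4 in water)
# density: 1.1556
# composition: barium_sulfate 0.1731, water 0.8269
# edges: 2.4720 5.2470 5.6240 5.9890 37.4410
# columns: energy_keV mass_attenuation_cm2_g
1.0000 6.315887e+03
1.5000 2.179424e+03
2.0000 1.008418e+03
2.4720 5.670563e+02
2.4720 6.245662e+02
2.5000 6.057561e+02
3.0000 3.694800e+02
3.5000 2.421452e+02
4.0000 1.681078e+02
4.5000 1.217049e+02
5.0000 9.124352e+01
5.2470 7.991346e+01
5.2470 1.262517e+02
5.5000 1.113160e+02
5.6240 1.048798e+02
5.6240 1.333505e+02
5.9890 1.129302e+02
5.9890 1.265117e+02
6.0000 1.258393e+02
6.5000 9.970354e+01
7.0000 8.038370e+01
7.5000 6.578741e+01
8.0000 5.454967e+01
8.5000 4.576987e+01
9.0000 3.879464e+01
9.5000 3.318115e+01
10.0000 2.861116e+01
10.5000 2.487459e+01
11.0000 2.176910e+01
11.5000 1.916614e+01
12.0000 1.696746e+01
12.5000 1.509707e+01
13.0000 1.349556e+01
13.5000 1.211601e+01
14.0000 1.092102e+01
14.5000 9.880564e+00
15.0000 8.970279e+00
15.5000 8.182184e+00
16.0000 7.485743e+00
16.5000 6.867895e+00
17.0000 6.317763e+00
17.5000 5.826235e+00
18.0000 5.385642e+00
18.5000 4.989494e+00
19.0000 4.632273e+00
19.5000 4.309270e+00
20.0000 4.016446e+00
20.5000 3.759589e+00
21.0000 3.525200e+00
21.5000 3.310834e+00
22.0000 3.114362e+00
22.5000 2.933924e+00
23.0000 2.767887e+00
23.5000 2.614819e+00
24.0000 2.473455e+00
24.5000 2.342677e+00
25.0000 2.221495e+00
25.5000 2.109027e+00
26.0000 2.004490e+00
26.5000 1.907183e+00
27.0000 1.816481e+00
27.5000 1.731820e+00
28.0000 1.652697e+00
28.5000 1.578656e+00
29.0000 1.509289e+00
29.5000 1.444224e+00
30.0000 1.383126e+00
30.5000 1.329325e+00
31.0000 1.278651e+00
31.5000 1.230871e+00
32.0000 1.185774e+00
32.5000 1.143169e+00
33.0000 1.102879e+00
33.5000 1.064744e+00
34.0000 1.028617e+00
34.5000 9.943606e-01
35.0000 9.618523e-01
35.5000 9.309773e-01
36.0000 9.016303e-01
36.5000 8.737140e-01
37.0000 8.471389e-01
37.4410 8.247465e-01
37.4410 3.245092e+00
37.5000 3.230003e+00
38.0000 3.105927e+00
38.5000 2.988329e+00
39.0000 2.876791e+00
39.5000 2.770928e+00
40.0000 2.670381e+00
40.5000 2.575999e+00
41.0000 2.486250e+00
41.5000 2.400852e+00
42.0000 2.319543e+00
42.5000 2.242081e+00
43.0000 2.168240e+00
43.5000 2.097810e+00
44.0000 2.030596e+00
44.5000 1.966414e+00
45.0000 1.905096e+00
45.5000 1.846483e+00
46.0000 1.790425e+00
46.5000 1.736785e+00
47.0000 1.685433e+00
47.5000 1.636248e+00
48.0000 1.589115e+00
48.5000 1.543927e+00
49.0000 1.500586e+00
49.5000 1.458996e+00
50.0000 1.419070e+00
50.5000 1.381183e+00
51.0000 1.344785e+00
51.5000 1.309805e+00
52.0000 1.276172e+00
52.5000 1.243822e+00
53.0000 1.212694e+00
53.5000 1.182730e+00
54.0000 1.153876e+00
54.5000 1.126081e+00
55.0000 1.099295e+00
55.5000 1.073473e+00
56.0000 1.048572e+00
56.5000 1.026463e+00
57.0000 1.005964e+00
57.5000 9.861086e-01
58.0000 9.668704e-01
58.5000 9.482249e-01
59.0000 9.301486e-01
59.5000 9.126195e-01
60.0000 8.956161e-01
60.5000 8.793494e-01
61.0000 8.635644e-01
61.5000 8.482428e-01
62.0000 8.333673e-01
62.5000 8.189210e-01
63.0000 8.048882e-01
63.5000 7.912537e-01
64.0000 7.780029e-01
64.5000 7.651221e-01
65.0000 7.525979e-01
65.5000 7.404176e-01
66.0000 7.285691e-01
66.5000 7.170409e-01
67.0000 7.058216e-01
67.5000 6.949008e-01
68.0000 6.842682e-01
68.5000 6.739139e-01
69.0000 6.638286e-01
69.5000 6.540032e-01
70.0000 6.444292e-01
70.5000 6.350983e-01
71.0000 6.260024e-01
71.5000 6.171339e-01
72.0000 6.084855e-01
72.5000 6.000501e-01
73.0000 5.918210e-01
73.5000 5.837915e-01
74.0000 5.759555e-01
74.5000 5.683069e-01
75.0000 5.608398e-01
75.5000 5.535488e-01
76.0000 5.464284e-01
76.5000 5.394734e-01
77.0000 5.326789e-01
77.5000 5.260401e-01
78.0000 5.195522e-01
78.5000 5.132109e-01
79.0000 5.070119e-01
79.5000 5.009509e-01
80.0000 4.950240e-01
80.5000 4.893125e-01
81.0000 4.837263e-01
81.5000 4.782619e-01
82.0000 4.729157e-01
82.5000 4.676846e-01
83.0000 4.625652e-01
83.5000 4.575544e-01
84.0000 4.526493e-01
84.5000 4.478470e-01
85.0000 4.431445e-01
85.5000 4.385393e-01
86.0000 4.340287e-01
86.5000 4.296101e-01
87.0000 4.252811e-01
87.5000 4.210394e-01
88.0000 4.168825e-01
88.5000 4.128084e-01
89.0000 4.088148e-01
89.5000 4.048997e-01
90.0000 4.010610e-01
90.5000 3.972968e-01
91.0000 3.936052e-01
91.5000 3.899844e-01
92.0000 3.864325e-01
92.5000 3.829478e-01
93.0000 3.795287e-01
93.5000 3.761736e-01
94.0000 3.728808e-01
94.5000 3.696488e-01
95.0000 3.664763e-01
95.5000 3.633616e-01
96.0000 3.603035e-01
96.5000 3.573005e-01
97.0000 3.543514e-01
97.5000 3.514549e-01
98.0000 3.486097e-01
98.5000 3.458147e-01
99.0000 3.430686e-01
99.5000 3.403704e-01
100.0000 3.377189e-01
100.5000 3.351366e-01
101.0000 3.325987e-01
101.5000 3.301041e-01
102.0000 3.276518e-01
102.5000 3.252410e-01
103.0000 3.228706e-01
103.5000 3.205398e-01
104.0000 3.182476e-01
104.5000 3.159933e-01
105.0000 3.137760e-01
105.5000 3.115949e-01
106.0000 3.094492e-01
106.5000 3.073382e-01
107.0000 3.052610e-01
107.5000 3.032171e-01
108.0000 3.012055e-01
108.5000 2.992258e-01
109.0000 2.972771e-01
109.5000 2.953589e-01
110.0000 2.934705e-01
110.5000 2.916113e-01
111.0000 2.897807e-01
111.5000 2.879781e-01
112.0000 2.862029e-01
112.5000 2.844546e-01
113.0000 2.827325e-01
113.5000 2.810363e-01
114.0000 2.793653e-01
114.5000 2.777191e-01
115.0000 2.760971e-01
115.5000 2.744989e-01
116.0000 2.729241e-01
116.5000 2.713720e-01
117.0000 2.698424e-01
117.5000 2.683348e-01
118.0000 2.668487e-01
118.5000 2.653837e-01
119.0000 2.639394e-01
119.5000 2.625154e-01
120.0000 2.611114e-01
120.5000 2.597269e-01
121.0000 2.583616e-01
121.5000 2.570152e-01
122.0000 2.556872e-01
122.5000 2.543773e-01
123.0000 2.530852e-01
123.5000 2.518106e-01
124.0000 2.505531e-01
124.5000 2.493125e-01
125.0000 2.480883e-01
125.5000 2.468804e-01
126.0000 2.456884e-01
126.5000 2.445120e-01
127.0000 2.433510e-01
127.5000 2.422051e-01
128.0000 2.410740e-01
128.5000 2.399574e-01
129.0000 2.388551e-01
129.5000 2.377669e-01
130.0000 2.366924e-01
130.5000 2.356316e-01
131.0000 2.345840e-01
131.5000 2.335495e-01
132.0000 2.325279e-01
132.5000 2.315189e-01
133.0000 2.305224e-01
133.5000 2.295381e-01
134.0000 2.285658e-01
134.5000 2.276053e-01
135.0000 2.266564e-01
135.5000 2.257189e-01
136.0000 2.247927e-01
136.5000 2.238774e-01
137.0000 2.229731e-01
137.5000 2.220794e-01
138.0000 2.211962e-01
138.5000 2.203234e-01
139.0000 2.194607e-01
139.5000 2.186080e-01
140.0000 2.177651e-01
140.5000 2.169320e-01
141.0000 2.161083e-01
141.5000 2.152940e-01
142.0000 2.144890e-01
142.5000 2.136930e-01
143.0000 2.129059e-01
143.5000 2.121277e-01
144.0000 2.113581e-01
144.5000 2.105970e-01
145.0000 2.098443e-01
145.5000 2.090999e-01
146.0000 2.083635e-01
146.5000 2.076352e-01
147.0000 2.069148e-01
147.5000 2.062022e-01
148.0000 2.054972e-01
148.5000 2.047997e-01
149.0000 2.041096e-01
149.5000 2.034269e-01
150.0000 2.027513e-01
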