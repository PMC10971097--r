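# name: copper
# density: 8.9600
# composition: Cu 1.0
# edges: 8.9790
# columns: energy_keV mass_attenuation_cm2_g
1.0000 1.057000e+04
1.5000 4.418000e+03
2.0000 2.154000e+03
2.5000 1.203512e+03
3.0000 7.480000e+02
3.5000 4.917946e+02
4.0000 3.420000e+02
4.5000 2.502869e+02
5.0000 1.893000e+02
5.5000 1.478579e+02
6.0000 1.180000e+02
6.5000 9.421848e+01
7.0000 7.649579e+01
7.5000 6.300650e+01
8.0000 5.255000e+01
8.5000 4.450754e+01
8.9790 3.830001e+01
8.9790 2.779999e+02
9.0000 2.764797e+02
9.5000 2.435253e+02
10.0000 2.159000e+02
10.5000 1.898154e+02
11.0000 1.678850e+02
11.5000 1.493012e+02
12.0000 1.334391e+02
12.5000 1.198104e+02
13.0000 1.080293e+02
13.5000 9.778787e+01
14.0000 8.883864e+01
14.5000 8.098072e+01
15.0000 7.405000e+01
15.5000 6.771550e+01
16.0000 6.209895e+01
16.5000 5.710020e+01
17.0000 5.263555e+01
17.5000 4.863464e+01
18.0000 4.503804e+01
18.5000 4.179531e+01
19.0000 3.886343e+01
19.5000 3.620555e+01
20.0000 3.379000e+01
20.5000 3.154373e+01
21.0000 2.949564e+01
21.5000 2.762413e+01
22.0000 2.591039e+01
22.5000 2.433797e+01
23.0000 2.289246e+01
23.5000 2.156118e+01
24.0000 2.033295e+01
24.5000 1.919789e+01
25.0000 1.814724e+01
25.5000 1.717322e+01
26.0000 1.626889e+01
26.5000 1.542808e+01
27.0000 1.464524e+01
27.5000 1.391542e+01
28.0000 1.323415e+01
28.5000 1.259742e+01
29.0000 1.200161e+01
29.5000 1.144346e+01
30.0000 1.092000e+01
30.5000 1.042394e+01
31.0000 9.957938e+00
31.5000 9.519733e+00
32.0000 9.107264e+00
32.5000 8.718652e+00
33.0000 8.352181e+00
33.5000 8.006283e+00
34.0000 7.679521e+00
34.5000 7.370577e+00
35.0000 7.078242e+00
35.5000 6.801406e+00
36.0000 6.539045e+00
36.5000 6.290216e+00
37.0000 6.054051e+00
37.5000 5.829746e+00
38.0000 5.616560e+00
38.5000 5.413806e+00
39.0000 5.220848e+00
39.5000 5.037095e+00
40.0000 4.862000e+00
40.5000 4.696799e+00
41.0000 4.539136e+00
41.5000 4.388582e+00
42.0000 4.244735e+00
42.5000 4.107223e+00
43.0000 3.975697e+00
43.5000 3.849831e+00
44.0000 3.729321e+00
44.5000 3.613882e+00
45.0000 3.503246e+00
45.5000 3.397165e+00
46.0000 3.295403e+00
46.5000 3.197741e+00
47.0000 3.103971e+00
47.5000 3.013900e+00
48.0000 2.927346e+00
48.5000 2.844135e+00
49.0000 2.764108e+00
49.5000 2.687111e+00
50.0000 2.613000e+00
50.5000 2.543371e+00
51.0000 2.476257e+00
51.5000 2.411543e+00
52.0000 2.349121e+00
52.5000 2.288889e+00
53.0000 2.230751e+00
53.5000 2.174615e+00
54.0000 2.120394e+00
54.5000 2.068006e+00
55.0000 2.017373e+00
55.5000 1.968422e+00
56.0000 1.921081e+00
56.5000 1.875285e+00
57.0000 1.830970e+00
57.5000 1.788075e+00
58.0000 1.746544e+00
58.5000 1.706321e+00
59.0000 1.667356e+00
59.5000 1.629598e+00
60.0000 1.593000e+00
60.5000 1.559530e+00
61.0000 1.527029e+00
61.5000 1.495463e+00
62.0000 1.464797e+00
62.5000 1.434999e+00
63.0000 1.406038e+00
63.5000 1.377882e+00
64.0000 1.350505e+00
64.5000 1.323879e+00
65.0000 1.297977e+00
65.5000 1.272775e+00
66.0000 1.248248e+00
66.5000 1.224373e+00
67.0000 1.201129e+00
67.5000 1.178494e+00
68.0000 1.156448e+00
68.5000 1.134972e+00
69.0000 1.114046e+00
69.5000 1.093653e+00
70.0000 1.073775e+00
70.5000 1.054397e+00
71.0000 1.035501e+00
71.5000 1.017073e+00
72.0000 9.990980e-01
72.5000 9.815617e-01
73.0000 9.644507e-01
73.5000 9.477517e-01
74.0000 9.314521e-01
74.5000 9.155398e-01
75.0000 9.000031e-01
75.5000 8.848306e-01
76.0000 8.700116e-01
76.5000 8.555354e-01
77.0000 8.413922e-01
77.5000 8.275720e-01
78.0000 8.140655e-01
78.5000 8.008637e-01
79.0000 7.879577e-01
79.5000 7.753392e-01
80.0000 7.630000e-01
80.5000 7.522220e-01
81.0000 7.416616e-01
81.5000 7.313130e-01
82.0000 7.211708e-01
82.5000 7.112297e-01
83.0000 7.014844e-01
83.5000 6.919300e-01
84.0000 6.825616e-01
84.5000 6.733745e-01
85.0000 6.643642e-01
85.5000 6.555263e-01
86.0000 6.468564e-01
86.5000 6.383505e-01
87.0000 6.300044e-01
87.5000 6.218144e-01
88.0000 6.137766e-01
88.5000 6.058874e-01
89.0000 5.981432e-01
89.5000 5.905405e-01
90.0000 5.830760e-01
90.5000 5.757465e-01
91.0000 5.685487e-01
91.5000 5.614795e-01
92.0000 5.545361e-01
92.5000 5.477155e-01
93.0000 5.410149e-01
93.5000 5.344315e-01
94.0000 5.279627e-01
94.5000 5.216059e-01
95.0000 5.153586e-01
95.5000 5.092183e-01
96.0000 5.031827e-01
96.5000 4.972494e-01
97.0000 4.914162e-01
97.5000 4.856808e-01
98.0000 4.800413e-01
98.5000 4.744954e-01
99.0000 4.690412e-01
99.5000 4.636767e-01
100.0000 4.584000e-01
100.5000 4.543222e-01
101.0000 4.503007e-01
101.5000 4.463343e-01
102.0000 4.424221e-01
102.5000 4.385631e-01
103.0000 4.347563e-01
103.5000 4.310007e-01
104.0000 4.272955e-01
104.5000 4.236396e-01
105.0000 4.200322e-01
105.5000 4.164725e-01
106.0000 4.129595e-01
106.5000 4.094926e-01
107.0000 4.060707e-01
107.5000 4.026932e-01
108.0000 3.993593e-01
108.5000 3.960682e-01
109.0000 3.928191e-01
109.5000 3.896114e-01
110.0000 3.864443e-01
110.5000 3.833172e-01
111.0000 3.802293e-01
111.5000 3.771800e-01
112.0000 3.741686e-01
112.5000 3.711945e-01
113.0000 3.682571e-01
113.5000 3.653558e-01
114.0000 3.624899e-01
114.5000 3.596589e-01
115.0000 3.568622e-01
115.5000 3.540992e-01
116.0000 3.513694e-01
116.5000 3.486723e-01
117.0000 3.460073e-01
117.5000 3.433739e-01
118.0000 3.407715e-01
118.5000 3.381998e-01
119.0000 3.356582e-01
119.5000 3.331463e-01
120.0000 3.306635e-01
120.5000 3.282094e-01
121.0000 3.257836e-01
121.5000 3.233856e-01
122.0000 3.210150e-01
122.5000 3.186714e-01
123.0000 3.163543e-01
123.5000 3.140634e-01
124.0000 3.117982e-01
124.5000 3.095584e-01
125.0000 3.073435e-01
125.5000 3.051532e-01
126.0000 3.029872e-01
126.5000 3.008450e-01
127.0000 2.987263e-01
127.5000 2.966308e-01
128.0000 2.945581e-01
128.5000 2.925079e-01
129.0000 2.904798e-01
129.5000 2.884736e-01
130.0000 2.864888e-01
130.5000 2.845253e-01
131.0000 2.825826e-01
131.5000 2.806606e-01
132.0000 2.787588e-01
132.5000 2.768770e-01
133.0000 2.750150e-01
133.5000 2.731724e-01
134.0000 2.713489e-01
134.5000 2.695444e-01
135.0000 2.677585e-01
135.5000 2.659909e-01
136.0000 2.642415e-01
136.5000 2.625099e-01
137.0000 2.607959e-01
137.5000 2.590994e-01
138.0000 2.574199e-01
138.5000 2.557574e-01
139.0000 2.541115e-01
139.5000 2.524821e-01
140.0000 2.508689e-01
140.5000 2.492717e-01
141.0000 2.476902e-01
141.5000 2.461244e-01
142.0000 2.445739e-01
142.5000 2.430386e-01
143.0000 2.415183e-01
143.5000 2.400127e-01
144.0000 2.385217e-01
144.5000 2.370451e-01
145.0000 2.355827e-01
145.5000 2.341343e-01
146.0000 2.326997e-01
146.5000 2.312788e-01
147.0000 2.298713e-01
147.5000 2.284771e-01
148.0000 2.270961e-01
148.5000 2.257280e-01
149.0000 2.243728e-01
149.5000 2.230302e-01
150.0000 2.217000e-01
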