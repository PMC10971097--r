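# name: trabecular bone (synthetic juvenile surrogate)
# density: 1.5000
# composition: bone_cortical 0.55, soft_tissue 0.45
# edges: 1.0721 1.3050 2.1455 2.4720 2.8220 3.6070 4.0380
# columns: energy_keV mass_attenuation_cm2_g
1.0000 4.058672e+03
1.0721 3.365137e+03
1.0721 3.376589e+03
1.3050 1.989342e+03
1.3050 1.996634e+03
1.5000 1.372532e+03
2.0000 6.103725e+02
2.1455 4.994400e+02
2.1455 6.769184e+02
2.4720 4.497578e+02
2.4720 4.570138e+02
2.5000 4.424094e+02
2.8220 3.119660e+02
2.8220 3.137959e+02
3.0000 2.630588e+02
3.5000 1.686595e+02
3.6070 1.546353e+02
3.6070 1.564184e+02
4.0000 1.160995e+02
4.0380 1.129540e+02
4.0380 2.546475e+02
4.5000 1.844561e+02
5.0000 1.348092e+02
5.5000 1.025520e+02
6.0000 7.989820e+01
6.5000 6.331626e+01
7.0000 5.105123e+01
7.5000 4.178036e+01
8.0000 3.463994e+01
8.5000 2.903435e+01
9.0000 2.458349e+01
9.5000 2.100374e+01
10.0000 1.809129e+01
10.5000 1.577213e+01
11.0000 1.383881e+01
11.5000 1.221370e+01
12.0000 1.083728e+01
12.5000 9.663384e+00
13.0000 8.655796e+00
13.5000 7.785846e+00
14.0000 7.030625e+00
14.5000 6.371675e+00
15.0000 5.794008e+00
15.5000 5.280118e+00
16.0000 4.826328e+00
16.5000 4.424039e+00
17.0000 4.066091e+00
17.5000 3.746493e+00
18.0000 3.460204e+00
18.5000 3.202961e+00
19.0000 2.971143e+00
19.5000 2.761660e+00
20.0000 2.571864e+00
20.5000 2.410147e+00
21.0000 2.262433e+00
21.5000 2.127207e+00
22.0000 2.003151e+00
22.5000 1.889112e+00
23.0000 1.784077e+00
23.5000 1.687158e+00
24.0000 1.597567e+00
24.5000 1.514611e+00
25.0000 1.437673e+00
25.5000 1.366204e+00
26.0000 1.299717e+00
26.5000 1.237774e+00
27.0000 1.179986e+00
27.5000 1.126001e+00
28.0000 1.075504e+00
28.5000 1.028211e+00
29.0000 9.838652e-01
29.5000 9.422359e-01
30.0000 9.031124e-01
30.5000 8.703800e-01
31.0000 8.394762e-01
31.5000 8.102693e-01
32.0000 7.826391e-01
32.5000 7.564756e-01
33.0000 7.316783e-01
33.5000 7.081546e-01
34.0000 6.858201e-01
34.5000 6.645966e-01
35.0000 6.444124e-01
35.5000 6.252016e-01
36.0000 6.069029e-01
36.5000 5.894601e-01
37.0000 5.728210e-01
37.5000 5.569374e-01
38.0000 5.417645e-01
38.5000 5.272607e-01
39.0000 5.133875e-01
39.5000 5.001090e-01
40.0000 4.873918e-01
40.5000 4.768046e-01
41.0000 4.666343e-01
41.5000 4.568590e-01
42.0000 4.474581e-01
42.5000 4.384125e-01
43.0000 4.297043e-01
43.5000 4.213166e-01
44.0000 4.132335e-01
44.5000 4.054402e-01
45.0000 3.979228e-01
45.5000 3.906681e-01
46.0000 3.836638e-01
46.5000 3.768981e-01
47.0000 3.703602e-01
47.5000 3.640396e-01
48.0000 3.579267e-01
48.5000 3.520120e-01
49.0000 3.462871e-01
49.5000 3.407434e-01
50.0000 3.353734e-01
50.5000 3.308935e-01
51.0000 3.265432e-01
51.5000 3.223171e-01
52.0000 3.182104e-01
52.5000 3.142184e-01
53.0000 3.103367e-01
53.5000 3.065610e-01
54.0000 3.028873e-01
54.5000 2.993118e-01
55.0000 2.958309e-01
55.5000 2.924410e-01
56.0000 2.891388e-01
56.5000 2.859211e-01
57.0000 2.827850e-01
57.5000 2.797275e-01
58.0000 2.767459e-01
58.5000 2.738375e-01
59.0000 2.709998e-01
59.5000 2.682303e-01
60.0000 2.655269e-01
60.5000 2.633709e-01
61.0000 2.612603e-01
61.5000 2.591939e-01
62.0000 2.571701e-01
62.5000 2.551878e-01
63.0000 2.532457e-01
63.5000 2.513427e-01
64.0000 2.494775e-01
64.5000 2.476492e-01
65.0000 2.458566e-01
65.5000 2.440987e-01
66.0000 2.423746e-01
66.5000 2.406833e-01
67.0000 2.390239e-01
67.5000 2.373955e-01
68.0000 2.357973e-01
68.5000 2.342284e-01
69.0000 2.326881e-01
69.5000 2.311756e-01
70.0000 2.296901e-01
70.5000 2.282310e-01
71.0000 2.267976e-01
71.5000 2.253892e-01
72.0000 2.240051e-01
72.5000 2.226448e-01
73.0000 2.213076e-01
73.5000 2.199930e-01
74.0000 2.187004e-01
74.5000 2.174292e-01
75.0000 2.161790e-01
75.5000 2.149491e-01
76.0000 2.137393e-01
76.5000 2.125488e-01
77.0000 2.113773e-01
77.5000 2.102244e-01
78.0000 2.090896e-01
78.5000 2.079724e-01
79.0000 2.068725e-01
79.5000 2.057895e-01
80.0000 2.047230e-01
80.5000 2.038914e-01
81.0000 2.030707e-01
81.5000 2.022604e-01
82.0000 2.014604e-01
82.5000 2.006706e-01
83.0000 1.998907e-01
83.5000 1.991205e-01
84.0000 1.983598e-01
84.5000 1.976085e-01
85.0000 1.968663e-01
85.5000 1.961332e-01
86.0000 1.954088e-01
86.5000 1.946932e-01
87.0000 1.939860e-01
87.5000 1.932872e-01
88.0000 1.925966e-01
88.5000 1.919140e-01
89.0000 1.912393e-01
89.5000 1.905724e-01
90.0000 1.899131e-01
90.5000 1.892613e-01
91.0000 1.886168e-01
91.5000 1.879795e-01
92.0000 1.873493e-01
92.5000 1.867261e-01
93.0000 1.861098e-01
93.5000 1.855001e-01
94.0000 1.848971e-01
94.5000 1.843006e-01
95.0000 1.837105e-01
95.5000 1.831267e-01
96.0000 1.825490e-01
96.5000 1.819775e-01
97.0000 1.814119e-01
97.5000 1.808522e-01
98.0000 1.802982e-01
98.5000 1.797500e-01
99.0000 1.792073e-01
99.5000 1.786702e-01
100.0000 1.781385e-01
100.5000 1.777257e-01
101.0000 1.773162e-01
101.5000 1.769101e-01
102.0000 1.765072e-01
102.5000 1.761076e-01
103.0000 1.757112e-01
103.5000 1.753179e-01
104.0000 1.749278e-01
104.5000 1.745407e-01
105.0000 1.741567e-01
105.5000 1.737756e-01
106.0000 1.733975e-01
106.5000 1.730223e-01
107.0000 1.726500e-01
107.5000 1.722806e-01
108.0000 1.719139e-01
108.5000 1.715500e-01
109.0000 1.711889e-01
109.5000 1.708304e-01
110.0000 1.704747e-01
110.5000 1.701215e-01
111.0000 1.697710e-01
111.5000 1.694230e-01
112.0000 1.690776e-01
112.5000 1.687347e-01
113.0000 1.683943e-01
113.5000 1.680563e-01
114.0000 1.677208e-01
114.5000 1.673876e-01
115.0000 1.670568e-01
115.5000 1.667284e-01
116.0000 1.664022e-01
116.5000 1.660784e-01
117.0000 1.657568e-01
117.5000 1.654374e-01
118.0000 1.651202e-01
118.5000 1.648052e-01
119.0000 1.644924e-01
119.5000 1.641817e-01
120.0000 1.638731e-01
120.5000 1.635666e-01
121.0000 1.632622e-01
121.5000 1.629598e-01
122.0000 1.626594e-01
122.5000 1.623610e-01
123.0000 1.620645e-01
123.5000 1.617700e-01
124.0000 1.614775e-01
124.5000 1.611868e-01
125.0000 1.608981e-01
125.5000 1.606112e-01
126.0000 1.603261e-01
126.5000 1.600429e-01
127.0000 1.597615e-01
127.5000 1.594819e-01
128.0000 1.592040e-01
128.5000 1.589279e-01
129.0000 1.586535e-01
129.5000 1.583809e-01
130.0000 1.581099e-01
130.5000 1.578406e-01
131.0000 1.575730e-01
131.5000 1.573070e-01
132.0000 1.570426e-01
132.5000 1.567799e-01
133.0000 1.565188e-01
133.5000 1.562592e-01
134.0000 1.560012e-01
134.5000 1.557447e-01
135.0000 1.554898e-01
135.5000 1.552364e-01
136.0000 1.549845e-01
136.5000 1.547341e-01
137.0000 1.544851e-01
137.5000 1.542376e-01
138.0000 1.539916e-01
138.5000 1.537470e-01
139.0000 1.535038e-01
139.5000 1.532620e-01
140.0000 1.530216e-01
140.5000 1.527825e-01
141.0000 1.525449e-01
141.5000 1.523085e-01
142.0000 1.520735e-01
142.5000 1.518399e-01
143.0000 1.516075e-01
143.5000 1.513765e-01
144.0000 1.511467e-01
144.5000 1.509182e-01
145.0000 1.506910e-01
145.5000 1.504651e-01
146.0000 1.502403e-01
146.5000 1.500168e-01
147.0000 1.497945e-01
147.5000 1.495735e-01
148.0000 1.493536e-01
148.5000 1.491349e-01
149.0000 1.489174e-01
149.5000 1.487010e-01
150.0000 1.484858e-01
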