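# name: tungsten
# density: 19.3000
# composition: W 1.0
# edges: 10.2070 11.5440 12.1000 69.5250
# columns: energy_keV mass_attenuation_cm2_g
1.0000 4.347990e+04
1.5000 1.547034e+04
2.0000 7.435373e+03
2.5000 4.214461e+03
3.0000 2.651880e+03
3.5000 1.793581e+03
4.0000 1.278992e+03
4.5000 9.496940e+02
5.0000 7.280592e+02
5.5000 5.727569e+02
6.0000 4.602948e+02
6.5000 3.765936e+02
7.0000 3.128384e+02
7.5000 2.633028e+02
8.0000 2.241484e+02
8.5000 1.927312e+02
9.0000 1.671862e+02
9.5000 1.461703e+02
10.0000 1.286981e+02
10.2070 1.223219e+02
10.2070 2.618434e+02
10.5000 2.438415e+02
11.0000 2.169091e+02
11.5000 1.939668e+02
11.5440 1.921133e+02
11.5440 2.668655e+02
12.0000 2.420059e+02
12.1000 2.369902e+02
12.1000 2.741196e+02
12.5000 2.513664e+02
13.0000 2.264313e+02
13.5000 2.047814e+02
14.0000 1.858846e+02
14.5000 1.693100e+02
15.0000 1.547059e+02
15.5000 1.417834e+02
16.0000 1.303033e+02
16.5000 1.200667e+02
17.0000 1.109070e+02
17.5000 1.026838e+02
18.0000 9.527865e+01
18.5000 8.859053e+01
19.0000 8.253332e+01
19.5000 7.703311e+01
20.0000 7.202629e+01
20.5000 6.745781e+01
21.0000 6.327995e+01
21.5000 5.945115e+01
22.0000 5.593507e+01
22.5000 5.269991e+01
23.0000 4.971768e+01
23.5000 4.696373e+01
24.0000 4.441625e+01
24.5000 4.205592e+01
25.0000 3.986558e+01
25.5000 3.782993e+01
26.0000 3.593532e+01
26.5000 3.416954e+01
27.0000 3.252162e+01
27.5000 3.098172e+01
28.0000 2.954099e+01
28.5000 2.819143e+01
29.0000 2.692582e+01
29.5000 2.573760e+01
30.0000 2.462086e+01
30.5000 2.357020e+01
31.0000 2.258072e+01
31.5000 2.164795e+01
32.0000 2.076782e+01
32.5000 1.993659e+01
33.0000 1.915086e+01
33.5000 1.840750e+01
34.0000 1.770363e+01
34.5000 1.703664e+01
35.0000 1.640408e+01
35.5000 1.580372e+01
36.0000 1.523350e+01
36.5000 1.469153e+01
37.0000 1.417604e+01
37.5000 1.368540e+01
38.0000 1.321810e+01
38.5000 1.277276e+01
39.0000 1.234806e+01
39.5000 1.194281e+01
40.0000 1.155588e+01
40.5000 1.118623e+01
41.0000 1.083290e+01
41.5000 1.049496e+01
42.0000 1.017158e+01
42.5000 9.861966e+00
43.0000 9.565378e+00
43.5000 9.281126e+00
44.0000 9.008564e+00
44.5000 8.747084e+00
45.0000 8.496118e+00
45.5000 8.255134e+00
46.0000 8.023629e+00
46.5000 7.801133e+00
47.0000 7.587205e+00
47.5000 7.381426e+00
48.0000 7.183406e+00
48.5000 6.992775e+00
49.0000 6.809185e+00
49.5000 6.632306e+00
50.0000 6.461830e+00
50.5000 6.297463e+00
51.0000 6.138928e+00
51.5000 5.985965e+00
52.0000 5.838325e+00
52.5000 5.695774e+00
53.0000 5.558090e+00
53.5000 5.425064e+00
54.0000 5.296496e+00
54.5000 5.172196e+00
55.0000 5.051987e+00
55.5000 4.935696e+00
56.0000 4.823163e+00
56.5000 4.714234e+00
57.0000 4.608763e+00
57.5000 4.506611e+00
58.0000 4.407645e+00
58.5000 4.311740e+00
59.0000 4.218775e+00
59.5000 4.128638e+00
60.0000 4.041217e+00
60.5000 3.956411e+00
61.0000 3.874120e+00
61.5000 3.794249e+00
62.0000 3.716707e+00
62.5000 3.641410e+00
63.0000 3.568274e+00
63.5000 3.497222e+00
64.0000 3.428176e+00
64.5000 3.361067e+00
65.0000 3.295824e+00
65.5000 3.232382e+00
66.0000 3.170678e+00
66.5000 3.110652e+00
67.0000 3.052245e+00
67.5000 2.995402e+00
68.0000 2.940070e+00
68.5000 2.886198e+00
69.0000 2.833737e+00
69.5000 2.782640e+00
69.5250 2.780121e+00
69.5250 1.254012e+01
70.0000 1.227827e+01
70.5000 1.201046e+01
71.0000 1.175039e+01
71.5000 1.149778e+01
72.0000 1.125237e+01
72.5000 1.101390e+01
73.0000 1.078214e+01
73.5000 1.055685e+01
74.0000 1.033780e+01
74.5000 1.012479e+01
75.0000 9.917609e+00
75.5000 9.716057e+00
76.0000 9.519946e+00
76.5000 9.329096e+00
77.0000 9.143332e+00
77.5000 8.962486e+00
78.0000 8.786398e+00
78.5000 8.614913e+00
79.0000 8.447882e+00
79.5000 8.285163e+00
80.0000 8.126618e+00
80.5000 7.972114e+00
81.0000 7.821524e+00
81.5000 7.674725e+00
82.0000 7.531600e+00
82.5000 7.392035e+00
83.0000 7.255921e+00
83.5000 7.123151e+00
84.0000 6.993625e+00
84.5000 6.867243e+00
85.0000 6.743913e+00
85.5000 6.623543e+00
86.0000 6.506044e+00
86.5000 6.391332e+00
87.0000 6.279326e+00
87.5000 6.169946e+00
88.0000 6.063117e+00
88.5000 5.958764e+00
89.0000 5.856817e+00
89.5000 5.757206e+00
90.0000 5.659867e+00
90.5000 5.564734e+00
91.0000 5.471746e+00
91.5000 5.380842e+00
92.0000 5.291966e+00
92.5000 5.205061e+00
93.0000 5.120072e+00
93.5000 5.036949e+00
94.0000 4.955639e+00
94.5000 4.876094e+00
95.0000 4.798267e+00
95.5000 4.722111e+00
96.0000 4.647582e+00
96.5000 4.574638e+00
97.0000 4.503236e+00
97.5000 4.433335e+00
98.0000 4.364898e+00
98.5000 4.297885e+00
99.0000 4.232261e+00
99.5000 4.167989e+00
100.0000 4.105035e+00
100.5000 4.043366e+00
101.0000 3.982949e+00
101.5000 3.923752e+00
102.0000 3.865745e+00
102.5000 3.808898e+00
103.0000 3.753183e+00
103.5000 3.698572e+00
104.0000 3.645037e+00
104.5000 3.595306e+00
105.0000 3.550173e+00
105.5000 3.505833e+00
106.0000 3.462270e+00
106.5000 3.419465e+00
107.0000 3.377403e+00
107.5000 3.336066e+00
108.0000 3.295439e+00
108.5000 3.255507e+00
109.0000 3.216254e+00
109.5000 3.177666e+00
110.0000 3.139728e+00
110.5000 3.102427e+00
111.0000 3.065750e+00
111.5000 3.029682e+00
112.0000 2.994212e+00
112.5000 2.959326e+00
113.0000 2.925013e+00
113.5000 2.891260e+00
114.0000 2.858056e+00
114.5000 2.825390e+00
115.0000 2.793250e+00
115.5000 2.761627e+00
116.0000 2.730508e+00
116.5000 2.699885e+00
117.0000 2.669747e+00
117.5000 2.640085e+00
118.0000 2.610888e+00
118.5000 2.582148e+00
119.0000 2.553856e+00
119.5000 2.526002e+00
120.0000 2.498579e+00
120.5000 2.471577e+00
121.0000 2.444989e+00
121.5000 2.418807e+00
122.0000 2.393022e+00
122.5000 2.367627e+00
123.0000 2.342614e+00
123.5000 2.317977e+00
124.0000 2.293708e+00
124.5000 2.269800e+00
125.0000 2.246246e+00
125.5000 2.223040e+00
126.0000 2.200175e+00
126.5000 2.177645e+00
127.0000 2.155444e+00
127.5000 2.133564e+00
128.0000 2.112002e+00
128.5000 2.090750e+00
129.0000 2.069803e+00
129.5000 2.049156e+00
130.0000 2.028803e+00
130.5000 2.008739e+00
131.0000 1.988958e+00
131.5000 1.969456e+00
132.0000 1.950227e+00
132.5000 1.931267e+00
133.0000 1.912570e+00
133.5000 1.894133e+00
134.0000 1.875951e+00
134.5000 1.858018e+00
135.0000 1.840332e+00
135.5000 1.822887e+00
136.0000 1.805680e+00
136.5000 1.788705e+00
137.0000 1.771960e+00
137.5000 1.755441e+00
138.0000 1.739142e+00
138.5000 1.723062e+00
139.0000 1.707195e+00
139.5000 1.691539e+00
140.0000 1.676090e+00
140.5000 1.660844e+00
141.0000 1.645798e+00
141.5000 1.630948e+00
142.0000 1.616292e+00
142.5000 1.601827e+00
143.0000 1.587548e+00
143.5000 1.573453e+00
144.0000 1.559539e+00
144.5000 1.545803e+00
145.0000 1.532243e+00
145.5000 1.518854e+00
146.0000 1.505635e+00
146.5000 1.492583e+00
147.0000 1.479695e+00
147.5000 1.466968e+00
148.0000 1.454401e+00
148.5000 1.441989e+00
149.0000 1.429732e+00
149.5000 1.417626e+00
150.0000 1.405669e+00
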