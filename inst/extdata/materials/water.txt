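# name: water
# density: 1.0000
# composition: H 0.1119, O 0.8881
# edges: none
# columns: energy_keV mass_attenuation_cm2_g
1.0000 4.077187e+03
1.5000 1.375907e+03
2.0000 6.172592e+02
2.5000 3.254091e+02
3.0000 1.928693e+02
3.5000 1.225781e+02
4.0000 8.277738e+01
4.5000 5.828332e+01
5.0000 4.258691e+01
5.5000 3.199495e+01
6.0000 2.464560e+01
6.5000 1.936787e+01
7.0000 1.549646e+01
7.5000 1.259271e+01
8.0000 1.037240e+01
8.5000 8.653632e+00
9.0000 7.295904e+00
9.5000 6.209186e+00
10.0000 5.329097e+00
10.5000 4.631398e+00
11.0000 4.052076e+00
11.5000 3.566954e+00
12.0000 3.157560e+00
12.5000 2.809617e+00
13.0000 2.511965e+00
13.5000 2.255799e+00
14.0000 2.034105e+00
14.5000 1.841249e+00
15.0000 1.672671e+00
15.5000 1.538560e+00
16.0000 1.419214e+00
16.5000 1.312618e+00
17.0000 1.217083e+00
17.5000 1.131185e+00
18.0000 1.053714e+00
18.5000 9.836448e-01
19.0000 9.200960e-01
19.5000 8.623124e-01
20.0000 8.096424e-01
20.5000 7.717656e-01
21.0000 7.365947e-01
21.5000 7.038784e-01
22.0000 6.733940e-01
22.5000 6.449434e-01
23.0000 6.183500e-01
23.5000 5.934560e-01
24.0000 5.701197e-01
24.5000 5.482142e-01
25.0000 5.276250e-01
25.5000 5.082489e-01
26.0000 4.899927e-01
26.5000 4.727717e-01
27.0000 4.565094e-01
27.5000 4.411359e-01
28.0000 4.265878e-01
28.5000 4.128070e-01
29.0000 3.997406e-01
29.5000 3.873402e-01
30.0000 3.755613e-01
30.5000 3.682450e-01
31.0000 3.612003e-01
31.5000 3.544131e-01
32.0000 3.478699e-01
32.5000 3.415585e-01
33.0000 3.354671e-01
33.5000 3.295849e-01
34.0000 3.239018e-01
34.5000 3.184082e-01
35.0000 3.130951e-01
35.5000 3.079543e-01
36.0000 3.029776e-01
36.5000 2.981578e-01
37.0000 2.934878e-01
37.5000 2.889610e-01
38.0000 2.845712e-01
38.5000 2.803125e-01
39.0000 2.761793e-01
39.5000 2.721664e-01
40.0000 2.682689e-01
40.5000 2.657546e-01
41.0000 2.632969e-01
41.5000 2.608939e-01
42.0000 2.585437e-01
42.5000 2.562445e-01
43.0000 2.539947e-01
43.5000 2.517926e-01
44.0000 2.496367e-01
44.5000 2.475254e-01
45.0000 2.454574e-01
45.5000 2.434314e-01
46.0000 2.414460e-01
46.5000 2.394999e-01
47.0000 2.375920e-01
47.5000 2.357212e-01
48.0000 2.338863e-01
48.5000 2.320862e-01
49.0000 2.303200e-01
49.5000 2.285867e-01
50.0000 2.268854e-01
50.5000 2.256776e-01
51.0000 2.244886e-01
51.5000 2.233181e-01
52.0000 2.221655e-01
52.5000 2.210303e-01
53.0000 2.199122e-01
53.5000 2.188108e-01
54.0000 2.177255e-01
54.5000 2.166562e-01
55.0000 2.156023e-01
55.5000 2.145635e-01
56.0000 2.135394e-01
56.5000 2.125298e-01
57.0000 2.115343e-01
57.5000 2.105526e-01
58.0000 2.095843e-01
58.5000 2.086292e-01
59.0000 2.076870e-01
59.5000 2.067574e-01
60.0000 2.058401e-01
60.5000 2.051602e-01
61.0000 2.044884e-01
61.5000 2.038243e-01
62.0000 2.031678e-01
62.5000 2.025189e-01
63.0000 2.018773e-01
63.5000 2.012429e-01
64.0000 2.006155e-01
64.5000 1.999951e-01
65.0000 1.993815e-01
65.5000 1.987746e-01
66.0000 1.981743e-01
66.5000 1.975804e-01
67.0000 1.969928e-01
67.5000 1.964114e-01
68.0000 1.958361e-01
68.5000 1.952668e-01
69.0000 1.947033e-01
69.5000 1.941457e-01
70.0000 1.935937e-01
70.5000 1.930473e-01
71.0000 1.925064e-01
71.5000 1.919709e-01
72.0000 1.914407e-01
72.5000 1.909157e-01
73.0000 1.903958e-01
73.5000 1.898810e-01
74.0000 1.893711e-01
74.5000 1.888661e-01
75.0000 1.883659e-01
75.5000 1.878704e-01
76.0000 1.873795e-01
76.5000 1.868933e-01
77.0000 1.864115e-01
77.5000 1.859341e-01
78.0000 1.854611e-01
78.5000 1.849925e-01
79.0000 1.845280e-01
79.5000 1.840677e-01
80.0000 1.836115e-01
80.5000 1.832373e-01
81.0000 1.828663e-01
81.5000 1.824983e-01
82.0000 1.821333e-01
82.5000 1.817712e-01
83.0000 1.814121e-01
83.5000 1.810558e-01
84.0000 1.807024e-01
84.5000 1.803518e-01
85.0000 1.800040e-01
85.5000 1.796588e-01
86.0000 1.793164e-01
86.5000 1.789766e-01
87.0000 1.786394e-01
87.5000 1.783048e-01
88.0000 1.779728e-01
88.5000 1.776432e-01
89.0000 1.773162e-01
89.5000 1.769915e-01
90.0000 1.766693e-01
90.5000 1.763495e-01
91.0000 1.760320e-01
91.5000 1.757169e-01
92.0000 1.754040e-01
92.5000 1.750934e-01
93.0000 1.747850e-01
93.5000 1.744789e-01
94.0000 1.741749e-01
94.5000 1.738731e-01
95.0000 1.735734e-01
95.5000 1.732757e-01
96.0000 1.729802e-01
96.5000 1.726867e-01
97.0000 1.723953e-01
97.5000 1.721058e-01
98.0000 1.718183e-01
98.5000 1.715328e-01
99.0000 1.712492e-01
99.5000 1.709675e-01
100.0000 1.706877e-01
100.5000 1.704240e-01
101.0000 1.701620e-01
101.5000 1.699017e-01
102.0000 1.696431e-01
102.5000 1.693862e-01
103.0000 1.691308e-01
103.5000 1.688772e-01
104.0000 1.686251e-01
104.5000 1.683746e-01
105.0000 1.681256e-01
105.5000 1.678783e-01
106.0000 1.676324e-01
106.5000 1.673881e-01
107.0000 1.671452e-01
107.5000 1.669039e-01
108.0000 1.666640e-01
108.5000 1.664256e-01
109.0000 1.661886e-01
109.5000 1.659530e-01
110.0000 1.657189e-01
110.5000 1.654861e-01
111.0000 1.652547e-01
111.5000 1.650247e-01
112.0000 1.647960e-01
112.5000 1.645687e-01
113.0000 1.643426e-01
113.5000 1.641179e-01
114.0000 1.638945e-01
114.5000 1.636724e-01
115.0000 1.634515e-01
115.5000 1.632319e-01
116.0000 1.630135e-01
116.5000 1.627964e-01
117.0000 1.625805e-01
117.5000 1.623658e-01
118.0000 1.621523e-01
118.5000 1.619399e-01
119.0000 1.617288e-01
119.5000 1.615188e-01
120.0000 1.613099e-01
120.5000 1.611022e-01
121.0000 1.608956e-01
121.5000 1.606902e-01
122.0000 1.604858e-01
122.5000 1.602825e-01
123.0000 1.600804e-01
123.5000 1.598793e-01
124.0000 1.596792e-01
124.5000 1.594803e-01
125.0000 1.592823e-01
125.5000 1.590854e-01
126.0000 1.588895e-01
126.5000 1.586947e-01
127.0000 1.585008e-01
127.5000 1.583080e-01
128.0000 1.581161e-01
128.5000 1.579253e-01
129.0000 1.577354e-01
129.5000 1.575464e-01
130.0000 1.573584e-01
130.5000 1.571714e-01
131.0000 1.569853e-01
131.5000 1.568001e-01
132.0000 1.566158e-01
132.5000 1.564325e-01
133.0000 1.562501e-01
133.5000 1.560685e-01
134.0000 1.558879e-01
134.5000 1.557081e-01
135.0000 1.555292e-01
135.5000 1.553512e-01
136.0000 1.551740e-01
136.5000 1.549977e-01
137.0000 1.548223e-01
137.5000 1.546476e-01
138.0000 1.544738e-01
138.5000 1.543009e-01
139.0000 1.541287e-01
139.5000 1.539574e-01
140.0000 1.537868e-01
140.5000 1.536171e-01
141.0000 1.534481e-01
141.5000 1.532799e-01
142.0000 1.531125e-01
142.5000 1.529459e-01
143.0000 1.527801e-01
143.5000 1.526150e-01
144.0000 1.524506e-01
144.5000 1.522870e-01
145.0000 1.521242e-01
145.5000 1.519621e-01
146.0000 1.518007e-01
146.5000 1.516400e-01
147.0000 1.514800e-01
147.5000 1.513208e-01
148.0000 1.511623e-01
148.5000 1.510044e-01
149.0000 1.508473e-01
149.5000 1.506909e-01
150.0000 1.505351e-01
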