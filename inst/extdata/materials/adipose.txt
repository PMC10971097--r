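# name: adipose tissue (lard surrogate, ICRU-44)
# density: 0.9500
# composition: H 0.114, C 0.598, N 0.007, O 0.278, Na 0.001, S 0.001, Cl 0.001
# edges: 1.0721 2.4720 2.8220
# columns: energy_keV mass_attenuation_cm2_g
1.0000 2.630813e+03
1.0721 2.171082e+03
1.0721 2.178981e+03
1.5000 8.630975e+02
2.0000 3.802940e+02
2.4720 2.047587e+02
2.4720 2.071773e+02
2.5000 2.004759e+02
2.8220 1.407563e+02
2.8220 1.427900e+02
3.0000 1.194438e+02
3.5000 7.551114e+01
4.0000 5.076398e+01
4.5000 3.564253e+01
5.0000 2.598034e+01
5.5000 1.948618e+01
6.0000 1.498841e+01
6.5000 1.177669e+01
7.0000 9.421885e+00
7.5000 7.656434e+00
8.0000 6.307042e+00
8.5000 5.274371e+00
9.0000 4.457177e+00
9.5000 3.802003e+00
10.0000 3.270559e+00
10.5000 2.859476e+00
11.0000 2.516443e+00
11.5000 2.227815e+00
12.0000 1.983122e+00
12.5000 1.774235e+00
13.0000 1.594776e+00
13.5000 1.439689e+00
14.0000 1.304935e+00
14.5000 1.187254e+00
15.0000 1.083999e+00
15.5000 1.005734e+00
16.0000 9.356206e-01
16.5000 8.725884e-01
17.0000 8.157346e-01
17.5000 7.642939e-01
18.0000 7.176145e-01
18.5000 6.751384e-01
19.0000 6.363858e-01
19.5000 6.009427e-01
20.0000 5.684504e-01
20.5000 5.465740e-01
21.0000 5.261389e-01
21.5000 5.070173e-01
22.0000 4.890953e-01
22.5000 4.722713e-01
23.0000 4.564545e-01
23.5000 4.415633e-01
24.0000 4.275244e-01
24.5000 4.142717e-01
25.0000 4.017456e-01
25.5000 3.898919e-01
26.0000 3.786618e-01
26.5000 3.680105e-01
27.0000 3.578977e-01
27.5000 3.482861e-01
28.0000 3.391420e-01
28.5000 3.304344e-01
29.0000 3.221348e-01
29.5000 3.142173e-01
30.0000 3.066577e-01
30.5000 3.022144e-01
31.0000 2.979224e-01
31.5000 2.937740e-01
32.0000 2.897619e-01
32.5000 2.858796e-01
33.0000 2.821207e-01
33.5000 2.784793e-01
34.0000 2.749501e-01
34.5000 2.715277e-01
35.0000 2.682073e-01
35.5000 2.649845e-01
36.0000 2.618549e-01
36.5000 2.588144e-01
37.0000 2.558593e-01
37.5000 2.529859e-01
38.0000 2.501908e-01
38.5000 2.474709e-01
39.0000 2.448231e-01
39.5000 2.422446e-01
40.0000 2.397325e-01
40.5000 2.380958e-01
41.0000 2.364936e-01
41.5000 2.349246e-01
42.0000 2.333878e-01
42.5000 2.318820e-01
43.0000 2.304063e-01
43.5000 2.289597e-01
44.0000 2.275413e-01
44.5000 2.261501e-01
45.0000 2.247854e-01
45.5000 2.234462e-01
46.0000 2.221320e-01
46.5000 2.208418e-01
47.0000 2.195749e-01
47.5000 2.183308e-01
48.0000 2.171087e-01
48.5000 2.159080e-01
49.0000 2.147281e-01
49.5000 2.135684e-01
50.0000 2.124284e-01
50.5000 2.115748e-01
51.0000 2.107339e-01
51.5000 2.099052e-01
52.0000 2.090887e-01
52.5000 2.082838e-01
53.0000 2.074904e-01
53.5000 2.067081e-01
54.0000 2.059368e-01
54.5000 2.051761e-01
55.0000 2.044258e-01
55.5000 2.036856e-01
56.0000 2.029554e-01
56.5000 2.022349e-01
57.0000 2.015238e-01
57.5000 2.008220e-01
58.0000 2.001293e-01
58.5000 1.994455e-01
59.0000 1.987703e-01
59.5000 1.981037e-01
60.0000 1.974453e-01
60.5000 1.969178e-01
61.0000 1.963963e-01
61.5000 1.958806e-01
62.0000 1.953706e-01
62.5000 1.948662e-01
63.0000 1.943674e-01
63.5000 1.938739e-01
64.0000 1.933858e-01
64.5000 1.929028e-01
65.0000 1.924250e-01
65.5000 1.919521e-01
66.0000 1.914842e-01
66.5000 1.910212e-01
67.0000 1.905628e-01
67.5000 1.901091e-01
68.0000 1.896600e-01
68.5000 1.892154e-01
69.0000 1.887753e-01
69.5000 1.883394e-01
70.0000 1.879079e-01
70.5000 1.874805e-01
71.0000 1.870572e-01
71.5000 1.866380e-01
72.0000 1.862228e-01
72.5000 1.858115e-01
73.0000 1.854041e-01
73.5000 1.850004e-01
74.0000 1.846005e-01
74.5000 1.842043e-01
75.0000 1.838117e-01
75.5000 1.834226e-01
76.0000 1.830370e-01
76.5000 1.826549e-01
77.0000 1.822762e-01
77.5000 1.819008e-01
78.0000 1.815287e-01
78.5000 1.811598e-01
79.0000 1.807941e-01
79.5000 1.804316e-01
80.0000 1.800721e-01
80.5000 1.797493e-01
81.0000 1.794290e-01
81.5000 1.791114e-01
82.0000 1.787963e-01
82.5000 1.784837e-01
83.0000 1.781735e-01
83.5000 1.778658e-01
84.0000 1.775605e-01
84.5000 1.772575e-01
85.0000 1.769569e-01
85.5000 1.766585e-01
86.0000 1.763625e-01
86.5000 1.760686e-01
87.0000 1.757770e-01
87.5000 1.754876e-01
88.0000 1.752003e-01
88.5000 1.749151e-01
89.0000 1.746321e-01
89.5000 1.743511e-01
90.0000 1.740721e-01
90.5000 1.737951e-01
91.0000 1.735202e-01
91.5000 1.732472e-01
92.0000 1.729761e-01
92.5000 1.727070e-01
93.0000 1.724397e-01
93.5000 1.721743e-01
94.0000 1.719108e-01
94.5000 1.716491e-01
95.0000 1.713892e-01
95.5000 1.711310e-01
96.0000 1.708746e-01
96.5000 1.706200e-01
97.0000 1.703670e-01
97.5000 1.701158e-01
98.0000 1.698662e-01
98.5000 1.696183e-01
99.0000 1.693720e-01
99.5000 1.691274e-01
100.0000 1.688843e-01
100.5000 1.686380e-01
101.0000 1.683933e-01
101.5000 1.681501e-01
102.0000 1.679085e-01
102.5000 1.676684e-01
103.0000 1.674299e-01
103.5000 1.671928e-01
104.0000 1.669572e-01
104.5000 1.667231e-01
105.0000 1.664904e-01
105.5000 1.662592e-01
106.0000 1.660294e-01
106.5000 1.658009e-01
107.0000 1.655739e-01
107.5000 1.653482e-01
108.0000 1.651239e-01
108.5000 1.649010e-01
109.0000 1.646793e-01
109.5000 1.644590e-01
110.0000 1.642400e-01
110.5000 1.640222e-01
111.0000 1.638058e-01
111.5000 1.635906e-01
112.0000 1.633766e-01
112.5000 1.631639e-01
113.0000 1.629524e-01
113.5000 1.627421e-01
114.0000 1.625330e-01
114.5000 1.623251e-01
115.0000 1.621184e-01
115.5000 1.619128e-01
116.0000 1.617084e-01
116.5000 1.615051e-01
117.0000 1.613030e-01
117.5000 1.611019e-01
118.0000 1.609020e-01
118.5000 1.607032e-01
119.0000 1.605054e-01
119.5000 1.603087e-01
120.0000 1.601131e-01
120.5000 1.599186e-01
121.0000 1.597251e-01
121.5000 1.595326e-01
122.0000 1.593411e-01
122.5000 1.591507e-01
123.0000 1.589612e-01
123.5000 1.587728e-01
124.0000 1.585853e-01
124.5000 1.583989e-01
125.0000 1.582134e-01
125.5000 1.580288e-01
126.0000 1.578452e-01
126.5000 1.576626e-01
127.0000 1.574808e-01
127.5000 1.573000e-01
128.0000 1.571201e-01
128.5000 1.569412e-01
129.0000 1.567631e-01
129.5000 1.565859e-01
130.0000 1.564096e-01
130.5000 1.562342e-01
131.0000 1.560597e-01
131.5000 1.558860e-01
132.0000 1.557131e-01
132.5000 1.555411e-01
133.0000 1.553700e-01
133.5000 1.551997e-01
134.0000 1.550302e-01
134.5000 1.548615e-01
135.0000 1.546936e-01
135.5000 1.545266e-01
136.0000 1.543603e-01
136.5000 1.541948e-01
137.0000 1.540301e-01
137.5000 1.538662e-01
138.0000 1.537031e-01
138.5000 1.535407e-01
139.0000 1.533791e-01
139.5000 1.532182e-01
140.0000 1.530581e-01
140.5000 1.528987e-01
141.0000 1.527401e-01
141.5000 1.525821e-01
142.0000 1.524249e-01
142.5000 1.522685e-01
143.0000 1.521127e-01
143.5000 1.519576e-01
144.0000 1.518032e-01
144.5000 1.516496e-01
145.0000 1.514966e-01
145.5000 1.513443e-01
146.0000 1.511926e-01
146.5000 1.510417e-01
147.0000 1.508914e-01
147.5000 1.507417e-01
148.0000 1.505928e-01
148.5000 1.504444e-01
149.0000 1.502967e-01
149.5000 1.501497e-01
150.0000 1.500033e-01
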