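# name: soft tissue (ICRU-44)
# density: 1.0600
# composition: H 0.102, C 0.143, N 0.034, O 0.708, Na 0.002, P 0.003, S 0.003, Cl 0.002, K 0.003
# edges: 1.0721 2.1455 2.4720 2.8220 3.6070
# columns: energy_keV mass_attenuation_cm2_g
1.0000 3.725243e+03
1.0721 3.087825e+03
1.0721 3.103629e+03
1.5000 1.255287e+03
2.0000 5.611966e+02
2.1455 4.585083e+02
2.1455 4.676871e+02
2.4720 3.110366e+02
2.4720 3.182929e+02
2.5000 3.081476e+02
2.8220 2.174873e+02
2.8220 2.215549e+02
3.0000 1.858086e+02
3.5000 1.181608e+02
3.6070 1.081619e+02
3.6070 1.121247e+02
4.0000 8.278135e+01
4.5000 5.837752e+01
5.0000 4.271709e+01
5.5000 3.212705e+01
6.0000 2.477174e+01
6.5000 1.947673e+01
7.0000 1.559068e+01
7.5000 1.267459e+01
8.0000 1.044384e+01
8.5000 8.721193e+00
9.0000 7.359116e+00
9.5000 6.267942e+00
10.0000 5.383492e+00
10.5000 4.683160e+00
11.0000 4.101069e+00
11.5000 3.613160e+00
12.0000 3.201032e+00
12.5000 2.850451e+00
13.0000 2.550285e+00
13.5000 2.291738e+00
14.0000 2.067803e+00
14.5000 1.872845e+00
15.0000 1.702298e+00
15.5000 1.565755e+00
16.0000 1.444265e+00
16.5000 1.335770e+00
17.0000 1.238544e+00
17.5000 1.151133e+00
18.0000 1.072303e+00
18.5000 1.001005e+00
19.0000 9.363441e-01
19.5000 8.775487e-01
20.0000 8.239550e-01
20.5000 7.847967e-01
21.0000 7.485011e-01
21.5000 7.147958e-01
22.0000 6.834397e-01
22.5000 6.542193e-01
23.0000 6.269448e-01
23.5000 6.014469e-01
24.0000 5.775744e-01
24.5000 5.551918e-01
25.0000 5.341773e-01
25.5000 5.144215e-01
26.0000 4.958256e-01
26.5000 4.783003e-01
27.0000 4.617648e-01
27.5000 4.461456e-01
28.0000 4.313762e-01
28.5000 4.173957e-01
29.0000 4.041489e-01
29.5000 3.915849e-01
30.0000 3.796576e-01
30.5000 3.720196e-01
31.0000 3.646832e-01
31.5000 3.576317e-01
32.0000 3.508492e-01
32.5000 3.443210e-01
33.0000 3.380336e-01
33.5000 3.319744e-01
34.0000 3.261315e-01
34.5000 3.204938e-01
35.0000 3.150511e-01
35.5000 3.097938e-01
36.0000 3.047127e-01
36.5000 2.997995e-01
37.0000 2.950463e-01
37.5000 2.904455e-01
38.0000 2.859901e-01
38.5000 2.816737e-01
39.0000 2.774899e-01
39.5000 2.734329e-01
40.0000 2.694972e-01
40.5000 2.668593e-01
41.0000 2.642869e-01
41.5000 2.617774e-01
42.0000 2.593285e-01
42.5000 2.569379e-01
43.0000 2.546034e-01
43.5000 2.523231e-01
44.0000 2.500949e-01
44.5000 2.479170e-01
45.0000 2.457876e-01
45.5000 2.437051e-01
46.0000 2.416679e-01
46.5000 2.396744e-01
47.0000 2.377231e-01
47.5000 2.358128e-01
48.0000 2.339420e-01
48.5000 2.321095e-01
49.0000 2.303140e-01
49.5000 2.285545e-01
50.0000 2.268297e-01
50.5000 2.255743e-01
51.0000 2.243404e-01
51.5000 2.231273e-01
52.0000 2.219347e-01
52.5000 2.207618e-01
53.0000 2.196081e-01
53.5000 2.184731e-01
54.0000 2.173564e-01
54.5000 2.162574e-01
55.0000 2.151757e-01
55.5000 2.141108e-01
56.0000 2.130624e-01
56.5000 2.120299e-01
57.0000 2.110130e-01
57.5000 2.100113e-01
58.0000 2.090245e-01
58.5000 2.080521e-01
59.0000 2.070939e-01
59.5000 2.061494e-01
60.0000 2.052184e-01
60.5000 2.045123e-01
61.0000 2.038151e-01
61.5000 2.031268e-01
62.0000 2.024471e-01
62.5000 2.017758e-01
63.0000 2.011127e-01
63.5000 2.004578e-01
64.0000 1.998107e-01
64.5000 1.991714e-01
65.0000 1.985396e-01
65.5000 1.979153e-01
66.0000 1.972983e-01
66.5000 1.966884e-01
67.0000 1.960855e-01
67.5000 1.954894e-01
68.0000 1.949001e-01
68.5000 1.943174e-01
69.0000 1.937412e-01
69.5000 1.931713e-01
70.0000 1.926076e-01
70.5000 1.920501e-01
71.0000 1.914985e-01
71.5000 1.909528e-01
72.0000 1.904129e-01
72.5000 1.898787e-01
73.0000 1.893501e-01
73.5000 1.888269e-01
74.0000 1.883091e-01
74.5000 1.877966e-01
75.0000 1.872893e-01
75.5000 1.867871e-01
76.0000 1.862899e-01
76.5000 1.857976e-01
77.0000 1.853102e-01
77.5000 1.848275e-01
78.0000 1.843495e-01
78.5000 1.838762e-01
79.0000 1.834073e-01
79.5000 1.829429e-01
80.0000 1.824829e-01
80.5000 1.821018e-01
81.0000 1.817240e-01
81.5000 1.813495e-01
82.0000 1.809781e-01
82.5000 1.806099e-01
83.0000 1.802448e-01
83.5000 1.798828e-01
84.0000 1.795237e-01
84.5000 1.791676e-01
85.0000 1.788145e-01
85.5000 1.784642e-01
86.0000 1.781167e-01
86.5000 1.777721e-01
87.0000 1.774302e-01
87.5000 1.770911e-01
88.0000 1.767546e-01
88.5000 1.764208e-01
89.0000 1.760896e-01
89.5000 1.757609e-01
90.0000 1.754348e-01
90.5000 1.751112e-01
91.0000 1.747901e-01
91.5000 1.744714e-01
92.0000 1.741551e-01
92.5000 1.738412e-01
93.0000 1.735297e-01
93.5000 1.732205e-01
94.0000 1.729135e-01
94.5000 1.726088e-01
95.0000 1.723063e-01
95.5000 1.720060e-01
96.0000 1.717079e-01
96.5000 1.714120e-01
97.0000 1.711181e-01
97.5000 1.708264e-01
98.0000 1.705367e-01
98.5000 1.702490e-01
99.0000 1.699634e-01
99.5000 1.696797e-01
100.0000 1.693980e-01
100.5000 1.691333e-01
101.0000 1.688704e-01
101.5000 1.686092e-01
102.0000 1.683497e-01
102.5000 1.680919e-01
103.0000 1.678358e-01
103.5000 1.675813e-01
104.0000 1.673284e-01
104.5000 1.670772e-01
105.0000 1.668275e-01
105.5000 1.665794e-01
106.0000 1.663329e-01
106.5000 1.660879e-01
107.0000 1.658444e-01
107.5000 1.656025e-01
108.0000 1.653620e-01
108.5000 1.651230e-01
109.0000 1.648855e-01
109.5000 1.646494e-01
110.0000 1.644147e-01
110.5000 1.641814e-01
111.0000 1.639496e-01
111.5000 1.637191e-01
112.0000 1.634900e-01
112.5000 1.632622e-01
113.0000 1.630358e-01
113.5000 1.628107e-01
114.0000 1.625870e-01
114.5000 1.623645e-01
115.0000 1.621433e-01
115.5000 1.619234e-01
116.0000 1.617047e-01
116.5000 1.614873e-01
117.0000 1.612711e-01
117.5000 1.610562e-01
118.0000 1.608424e-01
118.5000 1.606299e-01
119.0000 1.604185e-01
119.5000 1.602083e-01
120.0000 1.599993e-01
120.5000 1.597915e-01
121.0000 1.595847e-01
121.5000 1.593791e-01
122.0000 1.591747e-01
122.5000 1.589713e-01
123.0000 1.587690e-01
123.5000 1.585678e-01
124.0000 1.583677e-01
124.5000 1.581687e-01
125.0000 1.579707e-01
125.5000 1.577738e-01
126.0000 1.575779e-01
126.5000 1.573830e-01
127.0000 1.571892e-01
127.5000 1.569964e-01
128.0000 1.568045e-01
128.5000 1.566137e-01
129.0000 1.564238e-01
129.5000 1.562349e-01
130.0000 1.560470e-01
130.5000 1.558601e-01
131.0000 1.556740e-01
131.5000 1.554890e-01
132.0000 1.553048e-01
132.5000 1.551216e-01
133.0000 1.549393e-01
133.5000 1.547579e-01
134.0000 1.545774e-01
134.5000 1.543977e-01
135.0000 1.542190e-01
135.5000 1.540411e-01
136.0000 1.538641e-01
136.5000 1.536880e-01
137.0000 1.535127e-01
137.5000 1.533383e-01
138.0000 1.531647e-01
138.5000 1.529920e-01
139.0000 1.528200e-01
139.5000 1.526489e-01
140.0000 1.524786e-01
140.5000 1.523091e-01
141.0000 1.521404e-01
141.5000 1.519725e-01
142.0000 1.518053e-01
142.5000 1.516390e-01
143.0000 1.514734e-01
143.5000 1.513086e-01
144.0000 1.511445e-01
144.5000 1.509812e-01
145.0000 1.508187e-01
145.5000 1.506569e-01
146.0000 1.504958e-01
146.5000 1.503354e-01
147.0000 1.501758e-01
147.5000 1.500169e-01
148.0000 1.498587e-01
148.5000 1.497012e-01
149.0000 1.495444e-01
149.5000 1.493883e-01
150.0000 1.492329e-01
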