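# name: cesium iodide
# density: 4.5100
# composition: Cs 0.5116, I 0.4884
# edges: 4.5570 4.8520 5.0120 5.1880 5.3590 5.7140 33.1690 35.9850
# columns: energy_keV mass_attenuation_cm2_g
1.0000 2.456355e+04
1.5000 8.743887e+03
2.0000 4.205482e+03
2.5000 2.385925e+03
3.0000 1.502933e+03
3.5000 1.017697e+03
4.0000 7.265903e+02
4.5000 5.401537e+02
4.5570 5.233276e+02
4.5570 8.133228e+02
4.8520 6.941572e+02
4.8520 8.753850e+02
5.0000 8.113174e+02
5.0120 8.064140e+02
5.0120 1.062172e+03
5.1880 9.732332e+02
5.1880 1.058791e+03
5.3590 9.688047e+02
5.3590 1.126927e+03
5.5000 1.050314e+03
5.7140 9.471218e+02
5.7140 1.022309e+03
6.0000 8.880517e+02
6.5000 7.051643e+02
7.0000 5.696870e+02
7.5000 4.671308e+02
8.0000 3.880257e+02
8.5000 3.260005e+02
9.0000 2.766594e+02
9.5000 2.369014e+02
10.0000 2.044956e+02
10.5000 1.778085e+02
11.0000 1.556248e+02
11.5000 1.370278e+02
12.0000 1.213164e+02
12.5000 1.079487e+02
13.0000 9.650059e+01
13.5000 8.663745e+01
14.0000 7.809241e+01
14.5000 7.065103e+01
15.0000 6.413955e+01
15.5000 5.841617e+01
16.0000 5.336439e+01
16.5000 4.888784e+01
17.0000 4.490637e+01
17.5000 4.135291e+01
18.0000 3.817105e+01
18.5000 3.531312e+01
19.0000 3.273862e+01
19.5000 3.041302e+01
20.0000 2.830674e+01
20.5000 2.639432e+01
21.0000 2.465379e+01
21.5000 2.306613e+01
22.0000 2.161479e+01
22.5000 2.028533e+01
23.0000 1.906512e+01
23.5000 1.794307e+01
24.0000 1.690944e+01
24.5000 1.595560e+01
25.0000 1.507395e+01
25.5000 1.425773e+01
26.0000 1.350092e+01
26.5000 1.279818e+01
27.0000 1.214471e+01
27.5000 1.153624e+01
28.0000 1.096893e+01
28.5000 1.043932e+01
29.0000 9.944301e+00
29.5000 9.481074e+00
30.0000 9.047102e+00
30.5000 8.640091e+00
31.0000 8.257959e+00
31.5000 7.898817e+00
32.0000 7.560944e+00
32.5000 7.242774e+00
33.0000 6.942877e+00
33.1690 6.845411e+00
33.1690 2.113260e+01
33.5000 2.050029e+01
34.0000 1.959225e+01
34.5000 1.873723e+01
35.0000 1.793144e+01
35.5000 1.717139e+01
35.9850 1.647483e+01
35.9850 2.959179e+01
36.0000 2.955338e+01
36.5000 2.830987e+01
37.0000 2.713488e+01
37.5000 2.602378e+01
38.0000 2.497232e+01
38.5000 2.397657e+01
39.0000 2.303291e+01
39.5000 2.213799e+01
40.0000 2.128872e+01
40.5000 2.048224e+01
41.0000 1.971592e+01
41.5000 1.898728e+01
42.0000 1.829406e+01
42.5000 1.763414e+01
43.0000 1.700556e+01
43.5000 1.640648e+01
44.0000 1.583521e+01
44.5000 1.529016e+01
45.0000 1.476984e+01
45.5000 1.427289e+01
46.0000 1.379800e+01
46.5000 1.334398e+01
47.0000 1.290969e+01
47.5000 1.249408e+01
48.0000 1.209616e+01
48.5000 1.171501e+01
49.0000 1.134976e+01
49.5000 1.099958e+01
50.0000 1.067303e+01
50.5000 1.036870e+01
51.0000 1.007607e+01
51.5000 9.794596e+00
52.0000 9.523738e+00
52.5000 9.263002e+00
53.0000 9.011915e+00
53.5000 8.770035e+00
54.0000 8.537670e+00
54.5000 8.328669e+00
55.0000 8.126705e+00
55.5000 7.931481e+00
56.0000 7.742712e+00
56.5000 7.560132e+00
57.0000 7.383483e+00
57.5000 7.212524e+00
58.0000 7.047025e+00
58.5000 6.886765e+00
59.0000 6.731536e+00
59.5000 6.581139e+00
60.0000 6.435385e+00
60.5000 6.294093e+00
61.0000 6.157091e+00
61.5000 6.024215e+00
62.0000 5.895309e+00
62.5000 5.770223e+00
63.0000 5.648815e+00
63.5000 5.530948e+00
64.0000 5.416492e+00
64.5000 5.305323e+00
65.0000 5.197321e+00
65.5000 5.092374e+00
66.0000 4.990372e+00
66.5000 4.891210e+00
67.0000 4.794790e+00
67.5000 4.701016e+00
68.0000 4.609795e+00
68.5000 4.521041e+00
69.0000 4.434669e+00
69.5000 4.350599e+00
70.0000 4.268753e+00
70.5000 4.189057e+00
71.0000 4.111440e+00
71.5000 4.035833e+00
72.0000 3.962170e+00
72.5000 3.890389e+00
73.0000 3.820429e+00
73.5000 3.752231e+00
74.0000 3.685740e+00
74.5000 3.620901e+00
75.0000 3.557663e+00
75.5000 3.495976e+00
76.0000 3.435791e+00
76.5000 3.377063e+00
77.0000 3.319747e+00
77.5000 3.263800e+00
78.0000 3.209181e+00
78.5000 3.155850e+00
79.0000 3.103768e+00
79.5000 3.052899e+00
80.0000 3.003207e+00
80.5000 2.954657e+00
81.0000 2.907217e+00
81.5000 2.860853e+00
82.0000 2.815536e+00
82.5000 2.771236e+00
83.0000 2.727923e+00
83.5000 2.685570e+00
84.0000 2.644150e+00
84.5000 2.603637e+00
85.0000 2.564005e+00
85.5000 2.525231e+00
86.0000 2.487291e+00
86.5000 2.450163e+00
87.0000 2.413823e+00
87.5000 2.378252e+00
88.0000 2.343429e+00
88.5000 2.309333e+00
89.0000 2.275945e+00
89.5000 2.243248e+00
90.0000 2.211222e+00
90.5000 2.179850e+00
91.0000 2.149116e+00
91.5000 2.119003e+00
92.0000 2.089494e+00
92.5000 2.060576e+00
93.0000 2.032232e+00
93.5000 2.004448e+00
94.0000 1.977211e+00
94.5000 1.950506e+00
95.0000 1.924321e+00
95.5000 1.898642e+00
96.0000 1.873458e+00
96.5000 1.848756e+00
97.0000 1.824524e+00
97.5000 1.800751e+00
98.0000 1.777426e+00
98.5000 1.754539e+00
99.0000 1.732078e+00
99.5000 1.710035e+00
100.0000 1.688398e+00
100.5000 1.667159e+00
101.0000 1.646308e+00
101.5000 1.625837e+00
102.0000 1.605735e+00
102.5000 1.585996e+00
103.0000 1.566611e+00
103.5000 1.547571e+00
104.0000 1.528869e+00
104.5000 1.510497e+00
105.0000 1.492448e+00
105.5000 1.474714e+00
106.0000 1.457290e+00
106.5000 1.440167e+00
107.0000 1.423339e+00
107.5000 1.406799e+00
108.0000 1.390542e+00
108.5000 1.374562e+00
109.0000 1.358852e+00
109.5000 1.343406e+00
110.0000 1.328219e+00
110.5000 1.313285e+00
111.0000 1.298599e+00
111.5000 1.284156e+00
112.0000 1.269951e+00
112.5000 1.255978e+00
113.0000 1.242233e+00
113.5000 1.228711e+00
114.0000 1.215408e+00
114.5000 1.202318e+00
115.0000 1.189438e+00
115.5000 1.176764e+00
116.0000 1.164290e+00
116.5000 1.152014e+00
117.0000 1.139931e+00
117.5000 1.128037e+00
118.0000 1.116328e+00
118.5000 1.104801e+00
119.0000 1.093453e+00
119.5000 1.082279e+00
120.0000 1.071277e+00
120.5000 1.060442e+00
121.0000 1.049772e+00
121.5000 1.039264e+00
122.0000 1.028914e+00
122.5000 1.018719e+00
123.0000 1.008677e+00
123.5000 9.987841e-01
124.0000 9.890378e-01
124.5000 9.794354e-01
125.0000 9.699741e-01
125.5000 9.606513e-01
126.0000 9.514644e-01
126.5000 9.424109e-01
127.0000 9.334883e-01
127.5000 9.246942e-01
128.0000 9.160262e-01
128.5000 9.074820e-01
129.0000 8.990594e-01
129.5000 8.907562e-01
130.0000 8.825702e-01
130.5000 8.744993e-01
131.0000 8.665414e-01
131.5000 8.586945e-01
132.0000 8.509566e-01
132.5000 8.433258e-01
133.0000 8.358002e-01
133.5000 8.283779e-01
134.0000 8.210572e-01
134.5000 8.138363e-01
135.0000 8.067133e-01
135.5000 7.996867e-01
136.0000 7.927547e-01
136.5000 7.859158e-01
137.0000 7.791683e-01
137.5000 7.725106e-01
138.0000 7.659413e-01
138.5000 7.594588e-01
139.0000 7.530617e-01
139.5000 7.467485e-01
140.0000 7.405178e-01
140.5000 7.343682e-01
141.0000 7.282985e-01
141.5000 7.223072e-01
142.0000 7.163931e-01
142.5000 7.105548e-01
143.0000 7.047912e-01
143.5000 6.991010e-01
144.0000 6.934831e-01
144.5000 6.879362e-01
145.0000 6.824592e-01
145.5000 6.770509e-01
146.0000 6.717104e-01
146.5000 6.664364e-01
147.0000 6.612279e-01
147.5000 6.560839e-01
148.0000 6.510033e-01
148.5000 6.459852e-01
149.0000 6.410285e-01
149.5000 6.361323e-01
150.0000 6.312957e-01
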