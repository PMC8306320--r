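index	wet_upper	wet_middle	wet_lower	dry_upper	dry_middle	dry_lower
TN	260	257	317	1010	534	524
TL	1389	896	1675	1.964	4638	4811
NL	480	316	493	4605	1452	1560
PL	909	580	1182	1.4359	3186	3251
NP	0.528	0.545	0.417	0.321	0.456	0.480
R	0.25	0.639	0.488	0.306	0.431	0.433
avgK	10.685	6.973	10.568	37.552	17.371	18.363
avgCC	0.342	0.299	0.264	0.426	0.416	0.221
APD	3.814	4.509	3.49	3.483	3.857	3.21
CD	0.067	0.071	0.068	0.117	0.075	0.061
GD	0.041	0.027	0.033	0.037	0.033	0.035
M	0.622	0.635	0.505	0.556	0.595	0.410
NM	12	31	10	26	29	10
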