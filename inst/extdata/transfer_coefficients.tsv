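population	name	value
e	P0	-50.0075218035179
e	P1	1.97623793869666
e	P2	4.83747744529447
e	P3	0.243665120707592
e	P4	1.22696720810114
e	P5	-50.6901593143066
e	P6	-0.0370990797835122
e	P7	0.402796032394079
e	P8	0.214909037044625
e	P9	-2.60550872148453
e	P10	0.580779090259107
i	P0	-50.8207089995301
i	P1	6.21315882614396
i	P2	4.32230848528282
i	P3	0.54409451296545
i	P4	-1.25923518329809
i	P5	-66.1809709429972
i	P6	-0.0572883267994977
i	P7	-1.56045132342667
i	P8	-1.4610193692864
i	P9	-3.02395353026234
i	P10	-3.30065759541871
norm	muV0	-60
norm	dmuV0	10
norm	sigmaV0	4
norm	dsigmaV0	6
norm	tauVN0	0.5
norm	dtauVN0	1
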