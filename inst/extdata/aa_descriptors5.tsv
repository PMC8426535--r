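aa	d1	d2	d3	d4	d5
A	0.0477	-0.0159	0.7729	0.025	-0.1839
R	-0.4198	-0.6778	-0.2345	0.0572	0.4654
N	-0.731	0.0772	-0.1781	-0.2771	0.0877
D	-0.8911	-0.1056	-0.0124	-0.1137	-0.3207
C	0.4114	0.4082	-0.3254	-0.682	-0.4226
Q	-0.3894	-0.4275	-0.0294	-0.001	-0.0457
E	-0.5915	-0.6539	0.4071	0.108	-0.417
G	-0.7295	0.9459	0.2917	-0.2786	0.2861
H	-0.0338	-0.3038	-0.3346	-0.1941	-0.0655
I	1	0.2037	0.19	0.1674	0.1372
L	0.867	-0.0173	0.582	0.2643	0.057
K	-0.5755	-0.6708	0.105	0.0991	0.3137
M	0.7668	-0.2825	0.0519	-0.0898	-0.327
F	0.9142	0.0453	-0.1631	0.124	0.0222
P	-0.7973	0.7419	-0.4289	0.9231	-0.3178
S	-0.5827	0.3385	0.1459	-0.1784	0.1419
T	-0.2227	0.252	0.0706	-0.0869	0.1668
W	0.8012	-0.1921	-0.6781	0.0415	-0.1147
Y	0.3687	0.0644	-0.5938	0.0571	0.339
V	0.7873	0.2701	0.3611	0.035	0.1982
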