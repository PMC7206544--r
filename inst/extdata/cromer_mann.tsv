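# Cromer-Mann analytic atomic form factors, International Tables (1992)
# 4-Gaussian + constant convention: f(q) = sum_i a_i * exp(-b_i * s^2) + c,  s = q / (4*pi)
# columns: element  Z  a1  a2  a3  a4  b1  b2  b3  b4  c
element	Z	a1	a2	a3	a4	b1	b2	b3	b4	c
H	1	0.493002	0.322912	0.140191	0.040810	10.5109	26.1257	3.14236	57.7997	0.003038
C	6	2.310000	1.020000	1.588600	0.865000	20.8439	10.2075	0.56870	51.6512	0.215600
N	7	12.212600	3.132200	2.012500	1.166300	0.0057	9.8933	28.99750	0.5826	-11.529000
O	8	3.048500	2.286800	1.546300	0.867000	13.2771	5.7011	0.32390	32.9089	0.250800
F	9	3.539200	2.641200	1.517000	1.024300	10.2825	4.2944	0.26150	26.1476	0.277600
S	16	6.905300	5.203400	1.437900	1.586300	1.4679	22.2151	0.25360	56.1720	0.866900
Cl	17	11.460400	7.196400	6.255600	1.645500	0.0104	1.1662	18.51940	47.7784	-9.557400
Fe	26	11.769500	7.357300	3.522200	2.304500	4.7611	0.3072	15.35350	76.8805	1.036900
Br	35	17.178900	5.235800	5.637700	3.985100	2.1723	16.5796	0.26090	41.4328	2.955700
Ru	44	19.267400	12.918200	4.863370	1.567560	0.80852	8.43467	24.79970	94.2928	5.378740
I	53	20.147200	18.994900	7.513800	2.273500	4.3470	0.3814	27.76600	66.8776	4.071200
Pt	78	27.005900	17.763900	15.713100	5.783700	1.51293	8.81174	0.42459	38.6103	11.688300
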