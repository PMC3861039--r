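aa	percent	count
A	7	735736
C	2.3	241742
D	4.7	493994
E	7.1	746246
F	3.7	388889
G	6.6	693694
H	2.6	273273
I	4.3	451952
K	5.7	599099
L	10	1051051
M	2.1	220721
N	3.6	378378
P	6.3	662162
Q	4.8	504505
R	5.6	588589
S	8.3	872372
T	5.3	557057
V	6	630631
W	1.2	126126
Y	2.7	283784
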