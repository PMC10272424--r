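label	name
1	Left-Cerebral-White-Matter
2	Left-Cerebral-Cortex
3	Left-Lateral-Ventricle
4	Left-Inf-Lat-Ventricle
5	Left-Cerebellum-White-Matter
6	Left-Cerebellum-Cortex
7	Left-Thalamus
8	Left-Caudate
9	Left-Putamen
10	Left-Pallidum
11	3rd-Ventricle
12	4th-Ventricle
13	Brain-Stem
14	Left-Hippocampus
15	Left-Amygdala
16	Left-Accumbens
17	Left-Ventral-DC
18	Left-Vessel
19	Left-Choroid-Plexus
20	Right-Cerebral-White-Matter
21	Right-Cerebral-Cortex
22	Right-Lateral-Ventricle
23	Right-Inf-Lat-Ventricle
24	Right-Cerebellum-White-Matter
25	Right-Cerebellum-Cortex
26	Right-Thalamus
27	Right-Caudate
28	Right-Putamen
29	Right-Pallidum
30	Right-Hippocampus
31	Right-Amygdala
32	Right-Accumbens
33	Right-Ventral-DC
34	Right-Vessel
35	Right-Choroid-Plexus
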