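label	name
1	Right hippocampus
2	Left hippocampus
3	Right amygdala
4	Left amygdala
5	Right anterior temporal lobe, medial part
6	Left anterior temporal lobe, medial part
7	Right anterior temporal lobe, lateral part
8	Left anterior temporal lobe, lateral part
9	Right parahippocampal and ambient gyri
10	Left parahippocampal and ambient gyri
11	Right superior temporal gyrus, posterior part
12	Left superior temporal gyrus, posterior part
13	Right middle and inferior temporal gyrus
14	Left middle and inferior temporal gyrus
15	Right fusiform gyrus
16	Left fusiform gyrus
17	Right cerebellum
18	Left cerebellum
19	Brainstem
20	Left insula
21	Right insula
22	Left lateral remainder of occipital lobe
23	Right lateral remainder of occipital lobe
24	Left cingulate gyrus, anterior part
25	Right cingulate gyrus, anterior part
26	Left cingulate gyrus, posterior part
27	Right cingulate gyrus, posterior part
28	Left middle frontal gyrus
29	Right middle frontal gyrus
30	Left posterior temporal lobe
31	Right posterior temporal lobe
32	Left inferolateral remainder of parietal lobe
33	Right inferolateral remainder of parietal lobe
34	Left caudate nucleus
35	Right caudate nucleus
36	Left nucleus accumbens
37	Right nucleus accumbens
38	Left putamen
39	Right putamen
40	Left thalamus
41	Right thalamus
42	Left pallidum
43	Right pallidum
44	Corpus callosum
45	Right lateral ventricle
46	Left lateral ventricle
47	Right lateral ventricle, temporal horn
48	Left lateral ventricle, temporal horn
49	Third ventricle
50	Left precentral gyrus
51	Right precentral gyrus
52	Left straight gyrus
53	Right straight gyrus
54	Left anterior orbital gyrus
55	Right anterior orbital gyrus
56	Left inferior frontal gyrus
57	Right inferior frontal gyrus
58	Left superior frontal gyrus
59	Right superior frontal gyrus
60	Left postcentral gyrus
61	Right postcentral gyrus
62	Left superior parietal gyrus
63	Right superior parietal gyrus
64	Left lingual gyrus
65	Right lingual gyrus
66	Left cuneus
67	Right cuneus
68	Left medial orbital gyrus
69	Right medial orbital gyrus
70	Left lateral orbital gyrus
71	Right lateral orbital gyrus
72	Left posterior orbital gyrus
73	Right posterior orbital gyrus
74	Left substantia nigra
75	Right substantia nigra
76	Left subgenual frontal cortex
77	Right subgenual frontal cortex
78	Left subcallosal area
79	Right subcallosal area
80	Left pre-subgenual frontal cortex
81	Right pre-subgenual frontal cortex
82	Left superior temporal gyrus, anterior part
83	Right superior temporal gyrus, anterior part
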