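name	start	end	category
47S	1	13351	precursor
45S	424	12990	precursor
47S-01	424	13351	precursor
47S-02	1	12990	precursor
34S	1	6459	aberrant
36S	1	6601	aberrant
36S-C	1	6153	aberrant
30S	424	6459	precursor
26S	1672	6459	precursor
21S	3655	6459	precursor
21S-C	3655	6150	precursor
21S_S	3655	6147	precursor
21S_L	3655	6153	precursor
18S-E	3655	5524	precursor
18S-E+10	3655	5534	extension-series
18S-E+24	3655	5548	extension-series
18S-E+36	3655	5560	extension-series
18S-E+40	3655	5564	extension-series
18S-E+78	3655	5602	extension-series
32S	6601	12990	precursor
12S	6601	7559	precursor
7S	6601	6861	precursor
18S	3655	5523	mature
5.8S	6601	6757	mature
28S	7925	12990	mature
5ETS-01	1	423	spacer-fragment
5ETS-A0-1	1672	3654	spacer-fragment
ITS1-2-B1	6460	6600	spacer-fragment
ITS2-4-3p	7560	7924	spacer-fragment
3ETS	12991	13351	spacer-fragment
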