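name	position	side	provenance
01	424	both	this-work
A0	1672	both	this-work
1	3655	both	this-work
3	5524	both	this-work
E	5588	end-generating	this-work
C	6150	end-generating	this-work
2	6459	both	this-work
B1	6601	start-generating	this-work
4'	6756	end-generating	this-work
4a	6862	both	this-work
4	7560	both	this-work
3'	7925	start-generating	this-work
02	12990	both	this-work
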