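label	start	end
N	1	19
M1	20	40
E1	41	75
M2	76	98
L	99	130
M3	131	153
E2	154	190
M4	191	213
C	214	273
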