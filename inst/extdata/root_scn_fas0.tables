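// Root stem-cell-niche model in table dialect; fas mutant: the SCR table is all stars.

table ARF : IAA
0 : 1
1 : 0

table AUXINS : AUXINS
0 : 0
1 : 1

table IAA : AUXINS
0 : 1
1 : 0

table JKD : SCR SHR
0 0 : 0
0 1 : 0
1 0 : 0
1 1 : 1

table MGP : SCR SHR WOX
0 0 0 : 0
0 0 1 : 0
0 1 0 : 0
0 1 1 : 0
1 0 0 : 0
1 0 1 : 0
1 1 0 : 1
1 1 1 : 0

table PLT : ARF
0 : 0
1 : 1

// SCR truth table under a fas loss-of-function background: SCR expression
// is deregulated, so every row is an indetermination.
table SCR : SHR SCR JKD MGP
0 0 0 0 : *
0 0 0 1 : *
0 0 1 0 : *
0 0 1 1 : *
0 1 0 0 : *
0 1 0 1 : *
0 1 1 0 : *
0 1 1 1 : *
1 0 0 0 : *
1 0 0 1 : *
1 0 1 0 : *
1 0 1 1 : *
1 1 0 0 : *
1 1 0 1 : *
1 1 1 0 : *
1 1 1 1 : *

table SHR : SHR
0 : 0
1 : 1

table WOX : ARF MGP SCR SHR WOX
0 0 0 0 0 : 0
0 0 0 0 1 : 0
0 0 0 1 0 : 0
0 0 0 1 1 : 0
0 0 1 0 0 : 0
0 0 1 0 1 : 0
0 0 1 1 0 : 0
0 0 1 1 1 : 0
0 1 0 0 0 : 0
0 1 0 0 1 : 0
0 1 0 1 0 : 0
0 1 0 1 1 : 0
0 1 1 0 0 : 0
0 1 1 0 1 : 0
0 1 1 1 0 : 0
0 1 1 1 1 : 0
1 0 0 0 0 : 0
1 0 0 0 1 : 0
1 0 0 1 0 : 0
1 0 0 1 1 : 0
1 0 1 0 0 : 0
1 0 1 0 1 : 0
1 0 1 1 0 : 1
1 0 1 1 1 : 1
1 1 0 0 0 : 0
1 1 0 0 1 : 0
1 1 0 1 0 : 0
1 1 0 1 1 : 0
1 1 1 0 0 : 0
1 1 1 0 1 : 0
1 1 1 1 0 : 0
1 1 1 1 1 : 1

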