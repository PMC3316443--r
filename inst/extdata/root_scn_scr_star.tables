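// Root stem-cell-niche model in table dialect, with the starred SCR row kept.

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

// SCR truth table over SHR, SCR, JKD, MGP; the starred row encodes the
// experimentally unresolved jkd background (SCR may or may not stay on).
table SCR : SHR SCR JKD MGP
0 0 0 0 : 0
0 0 0 1 : 0
0 0 1 0 : 0
0 0 1 1 : 0
0 1 0 0 : 0
0 1 0 1 : 0
0 1 1 0 : 0
0 1 1 1 : 0
1 0 0 0 : 0
1 0 0 1 : 0
1 0 1 0 : 0
1 0 1 1 : 0
1 1 0 0 : 1
1 1 0 1 : *
1 1 1 0 : 1
1 1 1 1 : 1

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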