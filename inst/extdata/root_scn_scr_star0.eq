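// Root stem-cell-niche model with the starred SCR table row resolved to 0:
// pointwise identical to the published equation
// SCR := SHR & SCR & (JKD | ~MGP).

PLT := ARF;
AUXINS := AUXINS;
IAA := ~AUXINS;
ARF := ~IAA;
SHR := SHR;
SCR := SHR & SCR & (JKD | ~MGP);
JKD := SHR & SCR;
MGP := SHR & SCR & ~WOX;
WOX := ARF & SHR & SCR & (~MGP | WOX);
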