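// Root gene regulatory network (A. thaliana root stem-cell niche),
// equations as published for the nine-gene Boolean model.
// SHR; without regulators
// Auxin; without regulators

PLT: = ARF;

AUXINS: = AUXINS;

IAA: = ~ AUXINS;

ARF: = ~ IAA;

SHR: = SHR;

SCR: = SHR & SCR & (JKD | ~MGP);

JKD: = SHR & SCR;

MGP: = SHR & SCR & ~ WOX;

WOX: = ARF & SHR & SCR & (~ MGP | WOX);
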