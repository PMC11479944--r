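# GluA2-like gating scheme (reference file for read_scheme_config)
#
# Tuning record: base rates were fitted numerically so that the packaged
# simulator reproduces, at pH 7.4, a weighted desensitization time
# constant of 14.3 ms with a 1.8% steady-state/peak ratio for a 200-ms
# 10 mM glutamate pulse, and a paired-pulse recovery time constant of
# 15.6 ms (Hodgkin-Huxley fit, slope 2).  The pH 5.5 factors were then
# fitted to give tau_w,des = 3.7 ms, tau_recovery = 28.8 ms and a 0.64x
# peak ratio.  Binding (26, 13 /mM/ms), unbinding (3, 6 /ms) and gating
# (6, 1.8 /ms) rates are generic fast-AMPAR values and were held fixed.
#
# rates are 1/ms at 1 mM; ligand_order is the power of [glutamate] (mM)

reference_pH 7.4
resting C0

[states]
C0 closed
C1 closed
C2 closed
O open
D1 desensitized
D2 desensitized
D0 desensitized

[rates]
from to rate ligand_order
C0 C1 26 1
C1 C0 3 0
C1 C2 13 1
C2 C1 6 0
C2 O 6 0
O C2 1.8 0
C1 D1 0.1615 0
C2 D2 0.0817 0
O D2 0.0637 0
D2 C2 0.0012 0
D2 D1 0.1169 0
D1 D2 13 1
D1 D0 0.1169 0
D0 D1 13 1
D0 C0 0.1564 0

[conductance]
O 20

[ph_modifiers]
pH from to factor
5.5 C1 D1 3.72
5.5 C2 D2 3.72
5.5 O D2 3.72
5.5 C2 O 0.456
5.5 D2 D1 0.557
5.5 D1 D0 0.557
5.5 D0 C0 0.557
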