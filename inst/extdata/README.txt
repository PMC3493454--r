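Worked six-group spectral-count fixture
=======================================

fixture_counts.tsv : groups x runs spectral counts (triplicate H2A.Z bait,
                     H2A comparator, GFP control)
fixture_design.tsv : the matching run design

Expected cascade verdicts under the default thresholds
(fold1 = 10 vs GFP, fold2 = 2 vs H2A, detection in >= 2 of 3 bait runs),
derived by exhaustive hand evaluation of the two rules on the summed
("amalgamated") counts:

group  bait sum  H2A sum  GFP sum  fold vs GFP  fold vs H2A  stage1  stage2
NUC001       60       30        3         20.0          2.0    pass   pass
NUC002       27        0        0          Inf          Inf    pass   pass
NUC003       93      165        6         15.5    93/165=0.5636 pass  fail (fold < 2)
NUC004        9        0        0          Inf          Inf    fail (1/3 bait runs)
NUC005       15        0        6          2.5          Inf    fail (fold < 10)
NUC006        0       15        9     0 (undef. vs none)  0    fail (absent from bait)

Funnel: 6 -> 3 -> 2.  Stage-1 survivors {1, 2, 3}; stage-2 survivors {1, 2}.
NUC001 sits exactly at the stage-2 threshold (fold 2.0): thresholds are
inclusive.

Per-condition detected sets (>= 1 spectrum in >= 1 run of the condition):
  H2A.Z {1,2,3,4,5}, H2A {1,3,6}, GFP {1,3,5,6}
Venn regions: H2A.Z-only 2 (NUC002, NUC004); H2A.Z&GFP-only 1 (NUC005);
H2A&GFP-only 1 (NUC006); all three 2 (NUC001, NUC003); remaining regions 0.
Region counts sum to 6, the size of the union.
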