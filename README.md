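# retromorf

Screening protein sequences for **MoRFs** and **retro-MoRFs** — short
binding segments in intrinsically disordered regions, and their reversed
twins.

## The problem

Intrinsically disordered regions (IDRs) mediate much of the protein
interaction network through *molecular recognition features* (MoRFs):
short, hydrophobic-rich segments that fold upon binding a partner. In a
per-residue disorder profile a MoRF appears as a **dip** — a low-scoring
run flanked by disordered sequence. Because reversing a sequence preserves
its composition and its coarse hydrophobic/charge pattern, the *reverse*
of a known binding segment (a **retro-MoRF**) found in another protein is
a candidate for sharing that segment's binding partners; amphipathic
helix faces and polyproline-II (SH3 class I `RxxPxxP` / class II `PxxPxR`)
ligands are the geometries most tolerant of reversal.

`retromorf` is for sequence analysts who want to run this screen
end-to-end, reproducibly, on their own FASTA files:

1. **Profile** disorder with a transparent scale-based profiler (windowed
   mean of the TOP-IDP propensity scale, window 21, order/disorder
   boundary 0.5) — a deliberate, auditable stand-in for trained
   predictors.
2. **Detect dips** (5–30 residues below threshold, ≥ 0.2 deeper than
   flanks of ≥ 10 disordered residues; terminal tails allowed) and rank
   them by depth and hydrophobic enrichment.
3. **Align** candidate fragments against a database in normal and
   reversed orientation with a deterministic Smith–Waterman (affine gaps,
   BLOSUM62, open 11 / extend 1).
4. **Assess significance** with seeded empirical E-values:
   `p_emp = (1 + #{shuffled-query scores ≥ observed}) / (n_shuffles + 1)`,
   `E = p_emp × database size`.
5. **Classify** every surviving hit with three criteria — identity
   strictly **> 60%**, hydrophobic/charge pattern similarity (class-match
   fraction **≥ 0.6**), and a disordered / disorder-flanked / tail context
   on the target (short inter-domain linkers and structured regions are
   rejected) — annotated with the helical hydrophobic moment and PPII
   motif hits.

## Worked example

Plant the reversed copy of a hydrophobic 15-mer inside a disordered
background sequence, then screen it back out of a small database:

```r
library(retromorf)

query   <- random_motif(15, seed = 9, id = "fragF")
bg      <- generate_background(400, seed = 31, id = "targetB")
planted <- plant_motif(bg, query, 180, reversed = TRUE, seed = 32)
db      <- c(list(planted$seq),
             lapply(1:3, function(i)
               generate_background(350, seed = 40 + i, id = paste0("decoy", i))))

res <- scan_database(query, db, "both", scan_params(seed = 7))
res
#> <scan_result> 5 prescan survivor(s) of 8 query-target pair(s)
#>   positives: 4
#>   query_id target_id orientation score identity_pct evalue                label
#> 1    fragF   targetB    reversed    91    100.00000  0.004 retro_morf_candidate
#> 2    fragF   targetB      normal    54     63.63636  0.060           morf_match
#> 3    fragF    decoy2      normal    21     60.00000  0.128             rejected
#> 4    fragF    decoy1      normal    13    100.00000  0.768           morf_match
#> 5    fragF    decoy1    reversed    13    100.00000  0.892 retro_morf_candidate

res$alignments[[1]]
#> <sw_alignment> fragF|rev vs targetB [reversed]
#>   score 91, identity 100.0%
#>   Q 1 LCLIMFWIFFWFMLF 15
#>   T 180 LCLIMFWIFFWFMLF 194
```

Reading the output: the planted retro-copy is the top hit — reversed
orientation, 100% identity over the full 15-mer at positions 180–194,
E = 0.004, all three criteria true, label `retro_morf_candidate`. The
remaining rows are short chance alignments: row 3 fails the strict
identity criterion (60.0% is *not* above 60%), and rows 4–5 are 3-residue
flukes whose E-values near 1 say "expected by chance" — the E-value
column, not the label alone, carries the confidence. `summarize_run(res)`
tabulates hits and positives per orientation and per query.

A command-line front end wrapping the same functions ships in
`inst/cli/retromorf` (`profile`, `morfs`, `scan`, `simulate`), with every
threshold overridable from a YAML config (`read_config()`).

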