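# frustrace

Per-residue analysis of protein receptors that combines **local
energetic frustration** (from structure) with **evolutionary
conservation** (from a sequence family), for structural biologists
studying how multi-specific binding proteins — calmodulin being the
canonical example — balance a stable folding scaffold against the
local energetic strain that promiscuous binding requires.

## The two scores and the six classes

**SRLF index.** For residue *i* with native identity *a<sub>i</sub>*,
the native single-residue energy is the sum of contact-potential terms
over its contacts, *E<sub>i</sub>* = Σ<sub>j</sub> ε(a<sub>i</sub>,
a<sub>j</sub>). Mutational decoys randomize only residue *i*'s
identity (geometry and neighbours fixed), and the single-residue-level
frustration index is the Z-score

> SRLF<sub>i</sub> = (⟨E<sub>decoy</sub>⟩ − E<sub>i</sub>) / σ(E<sub>decoy</sub>)

Residues are **MF** (minimally frustrated) above +1, **HF** (highly
frustrated) below −1, **N** (neutral) otherwise, boundaries strict.
Decoys can be sampled (seeded, N = 2000 by default) or enumerated
exactly; the pair potential is a replaceable 20×20 contact matrix
(packaged default: a documented hydropathy-derived quasichemical-style
potential).

**rvET score.** Given an alignment and a rooted tree over its records,
cutting the tree at its *n*−1 highest nodes splits the leaves into *n*
groups; the real-value Evolutionary-Trace-style rank of column *i* is

> ρ<sub>i</sub> = 1 + Σ<sub>n=1..N−1</sub> (1/n) Σ<sub>g</sub> H<sub>g</sub>(i)

with H<sub>g</sub>(i) the Shannon entropy of the column within group
*g* (gaps excluded). Invariant columns score exactly 1; a residue is
**C** (conserved) when ρ < 5, strictly, else **NC**.

Crossing the two states yields the six classes
`(MF, C) (HF, C) (HF, NC) (MF, NC) (N, C) (N, NC)`, tallied per
reference position across an ensemble of complexes ("MF in 53 out of
58 complexes"-style counts), with bound-vs-unbound deltas attributing
frustration changes to the binding interface and fixed-backbone
variant rescoring for point mutants.

## Worked example

Everything below is generated, scored and classified from one seed —
no downloads. The synthetic benchmark designs known MF/HF positions
into a receptor, binds it in 58 complexes, and simulates a 32-leaf
alignment with known invariant columns:

```r
library(frustrace)

em    <- default_energy_model(seed = 42, n_decoys = 2000)
bench <- synthetic_benchmark(n_res = 60, n_complexes = 58,
                             n_leaves = 32, seed = 42, em = em)

profiles <- lapply(bench$complexes, frustration_profile, em = em)
names(profiles) <- sprintf("cpx%02d", 1:58)

rho    <- rvet_scores(bench$sim$msa, tree = bench$sim$tree)$rvet
cutoff <- conservation_cutoff_from_distribution(rho)
cons   <- rvet_scores(bench$sim$msa, tree = bench$sim$tree, cutoff = cutoff)

tab <- aggregate_classes(profiles, cons)
residue_report(tab, bench$labels$position)
```

```
   position aa rvet state_cons n_MF n_N n_HF consensus_class
1         6  I 7.08         NC   58   0    0        (MF, NC)
2        11  K 1.00          C    0   0   58         (HF, C)
3        16  I 1.00          C   58   0    0         (MF, C)
...
10       51  R 5.46         NC    0   0   58        (HF, NC)
```

Each row is one designed position: `rvet`/`state_cons` give its
conservation rank and state, `n_MF/n_N/n_HF` count its frustration
states across the 58 complexes, and the consensus class is the modal
state crossed with conservation — here all 10 designed positions
recover their designed labels (e.g. position 16, designed minimally
frustrated on an invariant column, is MF in 58/58 complexes and
conserved: `(MF, C)`).

Rescoring a point variant with the backbone fixed:

```r
variant_scan(bench$receptor, em, "A", 11, "I")
#> variant A:11->I  srlf -1.43 (HF) -> 1.22 (MF), fold change 0.9
```

position 11 was designed highly frustrated (its native Lys is the
worst identity for its neighbourhood); replacing it with Ile flips it
to minimally frustrated.

The packaged 148-residue mature human calmodulin sequence
(`cam_sequence()`) carries the reference composition used in focused
reports: nine Met (positions 36, 51, 71, 72, 76, 109, 124, 144, 145 —
6% of the sequence) and nine Leu (4, 18, 32, 39, 48, 69, 105, 112,
116), with `residue_report()` restricting any class table to such
position sets.

File-level drivers (`run_simulate`, `run_frustration`,
`run_conservation`, `run_classify`) read and write PDB / FASTA /
Clustal / Newick / TSV, and `inst/cli/frustrace.R` exposes them as
shell subcommands.

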