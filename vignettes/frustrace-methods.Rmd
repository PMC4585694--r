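---
title: "Methods: local frustration, evolutionary conservation, and the six-class residue scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local frustration, evolutionary conservation, and the six-class residue scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Multi-specific binding proteins such as calmodulin (CaM) must balance
two pressures: a stable folding scaffold, and enough local energetic
"looseness" at binding surfaces to accommodate many different
partners. `frustrace` quantifies both axes per residue — local
energetic frustration from structure, evolutionary conservation from a
sequence family — and crosses them into a six-class scheme
`{MF, N, HF} x {C, NC}` that separates folding scaffold residues
(minimally frustrated, conserved) from modular binding residues
(minimally frustrated, non-conserved) and functionally strained sites
(highly frustrated). All stages run on synthetic ground-truth data, so
every claim the package makes about itself is testable offline.

## Single-residue mutational frustration

For residue $i$ with native identity $a_i$, the native single-residue
energy is the sum of contact-potential terms over its contact partners,

$$E_i = \sum_{j:(i,j)\in\mathcal{C}} \varepsilon(a_i, a_j),$$

including inter-chain contacts when the model is a complex. Mutational
decoys replace *only* residue $i$'s identity — geometry and all
neighbour identities stay native — with a random identity, and the
single-residue-level frustration (SRLF) index is the Z-score

$$\mathrm{SRLF}_i = \frac{\langle E_{\mathrm{decoy}}\rangle - E_i}
{\sigma(E_{\mathrm{decoy}})},$$

so a native identity more stabilizing than the random alternatives
scores positive. Classification uses strict cutoffs: minimally
frustrated (MF) above $+1$, highly frustrated (HF) below $-1$, neutral
(N) otherwise — the boundary values $\pm 1$ are neutral.

Numerical choices:

* $\sigma$ is the population standard deviation of the decoy set
  (divide by $N$), the usual convention for decoy-set Z-scores.
* $\sigma = 0$ (e.g. a residue with no contacts, or a flat potential
  row) is not an error: the residue gets SRLF $= 0$, state N, and a
  `degenerate` flag, so ensemble runs never crash on sparse chains.
* The default decoy count is $N = 2000$ per residue; the exhaustive
  mode (`method = "exact"`) enumerates all candidate identities with
  their policy weights in closed form and is both the internal test
  oracle and a user-facing option. Sampled and exact indices agree
  within 0.1 at $N = 5000$ on 50-residue test structures.
* Each residue draws from its own random stream derived from the
  global seed plus the residue's chain id and author number, so adding
  or removing residues never shifts another residue's draws, and
  identical inputs with an identical seed reproduce output files byte
  for byte. (A consequence: renaming a chain re-keys the sampled
  streams; exact-mode scores are unaffected.)

**Decoy identity policy.** "Random identities from the native state"
admits two readings, and both are implemented. The default,
`composition`, draws from the multiset of identities present in the
scored model (the complex composition for bound runs, the receptor
composition for unbound runs); `uniform20` draws uniformly over the 20
standard amino acids. One subtlety follows from the composition
reading: removing a contact-free target chain still changes the decoy
pool (its residues leave the composition), so the exact bound-unbound
null — a target with zero receptor contacts leaves the receptor
profile bit-identical — holds under `uniform20`, while under
`composition` the native energies and contacts are identical but the
Z-scores can shift slightly. The package's interface-null guarantees
are therefore stated (and tested) under `uniform20`.

## The energy model

The pair potential is a symmetric $20\times20$ contact matrix; any
whitespace-delimited matrix with one-letter headers can be supplied.
The packaged default is a hydropathy-derived quasichemical-style
potential built from the Kyte–Doolittle index,

$$\varepsilon(a,b) = -\bigl(2\,s_a s_b + 0.6\,[a=b]\bigr),
\qquad s_a = \frac{h_a + 4.5}{9} \in [0,1],$$

so mutual hydrophobic burial is stabilizing, polar/charged mixed
contacts are near-neutral, and like pairs get a small bonus. The
like-pair term matters structurally: a pure product form makes the
Z-score independent of how strongly a residue is packed (any common
rescaling of candidate energies cancels in a Z-score), whereas the
mixture ties the score to the actual neighbourhood. This default is a
deliberately simple, fully documented synthetic potential — it
reproduces the rank behaviour of knowledge-based contact matrices
(hydrophobic residues buried among hydrophobics score MF, misplaced
charges score HF) but not any published matrix's absolute values.
Consequently SRLF values on real PDB entries are comparable in rank
and class, not in absolute magnitude, to frustration servers built on
transferable force fields with burial and water-mediated terms; such
terms, and pairwise (configurational) frustration, are out of scope.

**Contacts.** Two residues are in contact when their representative
sites — C$\beta$, or C$\alpha$ for glycine and residues lacking a
C$\beta$ — lie within 6.5 Å; within a chain, pairs separated by fewer
than 2 positions in author numbering are excluded ($i, i\pm1$), while
inter-chain pairs are never distance-filtered by sequence separation.
Both parameters are exposed on the `EnergyModel`.

**Structure cleaning.** Hetero groups (waters, ions, ligands) and
hydrogens are removed; selenomethionine is recoded to Met before the
standard-20 filter; other non-standard residues are dropped with a
warning. Multi-model (NMR) files keep model 1 by default — the "best
representative conformer" annotation is not machine-readable across
deposition vintages, so the first model is the deterministic default,
with an explicit model-index override. Alternate locations resolve to
the highest-occupancy conformer, ties broken by label order. Author
residue numbering is preserved in all outputs.

## Real-value Evolutionary-Trace-style conservation

Given an alignment and a rooted tree over its records, level $n$
($n = 1 \dots N-1$ for $N$ leaves) partitions the leaves into $n$
groups by cutting the tree at its $n-1$ highest internal nodes (root
first, descending height; ties broken by deterministic preorder
index). The score of column $i$ is

$$\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g=1}^{n} H_g(i),$$

where $H_g(i)$ is the Shannon entropy (natural log) of the amino-acid
frequencies of column $i$ within group $g$, gaps excluded from the
frequencies and an all-gap group contributing zero. An invariant
column scores exactly 1; lower is more conserved. A residue is
conserved (C) when $\rho <$ cutoff, strictly, with default cutoff 5.
This $1/n$-weighted group-entropy sum is this package's concrete,
reproducible instantiation of the real-value Evolutionary Trace idea;
published rvET implementations may weight levels or treat gaps
differently, so cross-tool scores should be compared by rank, not
digit.

Supporting choices:

* Trees are built by neighbor-joining on p-distances (fraction of
  mismatched columns where both sequences are ungapped), negative NJ
  branch lengths clamped to zero, midpoint-rooted — deterministic
  given the alignment. Externally built Newick trees are accepted and
  validated against the record ids.
* Columns where the reference sequence is gapped are absent from the
  profile; profiles are indexed by reference positions.
* Homolog-set filtering drops candidates identical to the reference
  and candidates shorter than 0.8 of its length, mirroring standard
  practice for trace analyses; homolog retrieval and alignment
  construction themselves are out of scope (the module consumes a
  ready MSA).
* The fixed cutoff 5 is calibrated to large (hundreds-of-sequences)
  natural homolog sets. Synthetic benchmarks instead pick the cutoff
  from the simulated score distribution via
  `conservation_cutoff_from_distribution()`: 2-means clustering of the
  scores, cutoff at the midpoint of the empirical gap between the two
  clusters. The gap midpoint (rather than the midpoint of the cluster
  centers) is used because simulated score distributions are strongly
  skewed — invariant columns sit exactly at 1 while diverged columns
  spread widely — and a center midpoint can land inside the upper
  cluster.

## The six-class table and ensemble aggregation

Each complex's receptor chain is mapped to the reference sequence by
global alignment (match $+1$, mismatch $0$, gap $-1$); mappings below
60% identity are refused with a warning, and unmapped residues are
reported separately rather than dropped. Conservation is computed once
per reference and shared by all complexes. Per reference position the
table reports per-complex SRLF values and classes, "x out of y"
ensemble counts (`n_MF`, `n_N`, `n_HF`), and a consensus: the modal
frustration state across complexes, ties resolved to neutral — a
deliberately conservative rule, emitted alongside the raw counts so no
information is lost. Class-population fractions are emitted per
complex and pooled, and the 2D map/histogram tables report both
per-(residue, complex) points and per-residue means, since either view
is a legitimate rendering of an ensemble scatter.

Variant rescoring (`variant_scan()`) replaces one identity in sequence
only, keeping the backbone fixed, and rescores that position under the
same random stream; the fold change $|z_{\mathrm{mut}}|/|z_{\mathrm{wt}}|$
is flagged undefined at $z_{\mathrm{wt}} = 0$. Fixed-backbone
relabeling stands in for full homology remodeling of point variants;
it is exact for the contact-graph energy model used here (a point
mutation does not move the template backbone), but ignores real
side-chain repacking.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has ground truth:

* **Structures** are deterministic helical arcs (2.3 Å C$\alpha$
  radius, 1.45 Å rise, 100° twist, C$\beta$ 1.5 Å radially outward),
  giving each interior residue contacts at $i\pm3$ and $i\pm4$ — a
  contact graph, not physical geometry. Same seed, same file,
  bit-identical; different seed, different sequence on the same
  template.
* **Designed frustration**: at MF-designed positions the identity
  minimizing the native contact energy given the neighbours is
  assigned iteratively (HF symmetric, at most 10 fixed-order sweeps),
  and local optimality is re-verified after convergence. Default
  designed positions are spaced 5 apart, beyond the $i\pm3/i\pm4$
  contact shell, so designs do not couple through shared contacts —
  interleaving designed positions at contact distance makes the sweep
  oscillate between mutually contradictory optima and voids the
  ground-truth labels.
* **Complexes** place one target residue 6 Å radially outward of each
  prescribed interface position; the realized inter-chain contact set
  is verified to equal the design, or the generator errors.
* **Alignments** evolve a root sequence down a (simulated coalescent
  or supplied) tree under uniform replacement: on a branch of length
  $b$ a column of rate $r$ is redrawn uniformly from the 20 amino
  acids with probability $1 - e^{-rb}$, which gives closed-form
  mismatch probabilities for testing. Invariant columns never change;
  no indels are introduced (gap handling is tested on hand-built
  gapped fixtures instead). The receptor's own sequence is grafted
  into the alignment as a zero-branch reference tip, mirroring an
  analysis where the reference sits in its homolog set.

The standard benchmark uses a 60-residue receptor, 58 complexes with
four-position interfaces, and a 32-leaf alignment with 30% invariant
columns — sizes chosen so the ensemble statistics are meaningful while
the whole benchmark runs in seconds. Passing it demonstrates that the
pipeline machinery recovers designed labels through every stage
(structure I/O, contacts, decoys, tree cuts, mapping, aggregation); it
does not demonstrate that the default potential ranks real proteins as
a molecular force field would, nor that simulated-alignment
conservation matches the statistics of natural homolog sets (no
indels, no rate autocorrelation, no composition bias).

## Known limitations

* The default energy model has no burial, secondary-structure,
  electrostatic or water-mediated terms; absolute SRLF values on real
  structures are not comparable to force-field-based frustration
  servers.
* The rvET weighting is one member of the Evolutionary-Trace family;
  integer ET and other published weightings are not implemented.
* mmCIF input, assembly generation and side-chain repacking are out of
  scope; PDB-format files only.
* Under the composition decoy policy, per-residue scores depend
  (weakly) on overall model composition; cross-complex comparisons
  should hold the policy and seed fixed, as the drivers do.
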