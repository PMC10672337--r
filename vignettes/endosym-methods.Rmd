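---
title: "Methods: codon bias, substitution rates and genetic-group classification in reduced endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon bias, substitution rates and genetic-group classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosym)
```

## The scientific problem

Obligate intracellular endosymbionts of insects — here the whitefly symbiont
*Candidatus* Portiera aleyrodidarum is the motivating system — are maternally
inherited and codiverge with their hosts. Their genomes are tiny (a few
hundred kilobases), extremely AT-rich, and densely coding. Comparative
questions about such panels are usually answered with a standard battery of
statistics: genome feature summaries, single-copy orthology, synonymous and
nonsynonymous substitution rates, codon-usage-bias analyses (PR2, neutrality
and ENC plots), and whole-genome relatedness (ANI, AAI, Mash distances) from
which lineages are partitioned into genetic groups. `endosym` implements this
battery end to end, together with a simulator that generates annotated
genome panels with known truth, so every stage can be validated without any
sequence downloads.

## Per-gene codon statistics

All per-gene statistics operate on sense-codon counts; a terminal stop codon
is stripped before counting, and stop codons never contribute to any
statistic. Translation uses the bacterial genetic code (table 11)
throughout.

* **Positional GC** — GC1, GC2, GC3 are the G+C fractions at each codon
  position; GC12 is the arithmetic mean of GC1 and GC2.
* **PR2 coordinates** — `x = G3/(G3+C3)` and `y = A3/(A3+T3)` over the third
  positions of all sense codons (not only fourfold-degenerate sites, which
  is the other convention in the literature; the all-sense-codon definition
  matches how third-position content is usually reported for these
  genomes). A zero denominator yields a missing coordinate and the gene is
  excluded from PR2 summaries, where it is counted as excluded.
* **GC3s** — GC at third positions of codons with synonymous alternatives:
  all sense codons except Met (ATG) and Trp (TGG). This definition is
  recorded in the pipeline manifest because tools differ in small details
  of the denominator.
* **ENC** — Wright's (1990) effective number of codons. For each
  amino-acid family with count `n >= 2` the codon homozygosity is
  `F = (n * sum(p_i^2) - 1) / (n - 1)`; the class means over families of
  degeneracy 2, 3, 4 and 6 (Leu, Ser and Arg each counted as one sixfold
  family, Ile the only threefold family) combine as
  `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. A missing threefold mean is
  imputed as the mean of the two- and fourfold means; the result is clamped
  to [20, 61]. The clamp matters: with finite counts the unclamped value of
  perfectly even usage slightly exceeds 61 because of the `n - 1`
  correction, and clamping reproduces the conventional limits exactly.

The ENC-plot reference curve is the no-selection expectation
`ENC_exp = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`; a gene is flagged as
below the curve when `(ENC_exp - ENC)/ENC_exp` exceeds a margin of 0.05
(5%), the conventional allowance for sampling noise.

## Group-level bias analyses

`pr2_summary()` reports the mean point, the quadrant occupancy around
(0.5, 0.5), and a 95% confidence ellipse computed as the chi-square (2 df,
0.95) contour of the two-dimensional sample covariance. Points exactly on a
quadrant boundary are assigned upper/right (`>= 0.5`); the tie rule is
arbitrary but deterministic.

`neutrality_fit()` regresses GC12 (response) on GC3 (predictor) by ordinary
least squares — the standard neutrality-plot direction; the literature
sometimes only says "between GC12 and GC3", so the direction is stated here
explicitly. `R^2` is the squared Pearson correlation; a constant response
has no explainable variance and is reported as `R^2 = 0`, while a constant
predictor is a degenerate regression and an error. Group-level fits pool
the per-gene points of all genomes in the group (rather than averaging per
genome first), consistent with the per-gene definition of the inputs.

## Orthology

Single-copy orthologs are found by reciprocal best hits (RBH) on global
protein alignments: Needleman–Wunsch with BLOSUM62 and affine gap penalties
(open 11, extend 1), implemented in C++. For each genome pair, each
protein's best hit is taken by alignment score, near-ties resolved by
alignment identity and then lexicographic locus id; *exact* ties (equal
score and identity, e.g. perfect duplicates) are treated as
indistinguishable and linked together, which makes the affected component
fail the single-copy filter — the conservative behaviour one wants for
Ka/Ks and ANI inputs. Mutual best hits become edges, connected components
become groups, and only components with exactly one member in every genome
are retained.

Two engineering choices keep the quadratic search exact but fast:
candidates are ranked by shared amino-acid 3-mer counts and only the top 8
are fully aligned, and candidates with fewer than half the leader's shared
3-mers are not aligned at all. At the identity levels of a congeneric panel
(>85% amino-acid identity between true orthologs) the true best hit is
always in this candidate set; the thresholds are exposed as arguments.

Downstream pairwise statistics use codon-aware alignments: the protein
alignment is mapped back onto codons, so gaps come in multiples of three
and the frame is preserved; only ungapped codon columns enter Ka/Ks, ANI
and AAI. This replaces multiple-alignment-plus-trimming pipelines, which
pairwise statistics do not need.

## Substitution rates (NG86)

Ka/Ks uses the Nei–Gojobori (1986) counting method with Jukes–Cantor
correction — the classical, fully specifiable default of the standard
toolkits. Per codon, each position contributes the fraction of its three
possible single-base changes that are synonymous (changes to stop codons
count as nonsynonymous); between codons, differences are averaged over all
minimal mutational pathways with equal weights, excluding pathways through
stop codons (if every pathway is blocked, all are used with stop steps
counted nonsynonymous). Site counts are averaged over the two sequences;
proportions are corrected by `K = -(3/4) log(1 - 4p/3)`, with `p >= 3/4`
reported as missing with a saturation flag. `kaks_vs_reference()` computes
one series per non-reference genome over all single-copy orthologs, the
design used to contrast within-group against between-group divergence.

## Relatedness and classification

* **ANI / AAI** are computed from the single-copy ortholog alignments (not
  from fragment mapping as in fastANI): per ortholog, nucleotide identity
  over ungapped codon columns (ANI) or residue identity over gap-free
  protein columns (AAI), combined as a length-weighted mean. Printed
  two-decimal values from fragment-based tools are therefore matched
  approximately, not bit-exactly.
* **Mash distance** uses a bottom-s MinHash sketch (k = 21, s = 1000, one
  fixed hash seed — the Mash/Mashtree defaults) of canonical k-mers, hashes
  masked to 53 bits so they survive R's doubles exactly. The Jaccard index
  is estimated from the joint bottom-s sketch and converted by
  `d = -log(2j/(1+j))/k`. By default the concatenated single-copy gene set
  of each genome is sketched (matching the "concatenated datasets" design);
  whole-genome sketching is available as an option.
* **Neighbor joining** is classical Saitou–Nei (via `ape::nj`); negative
  branch lengths, which NJ can produce on non-additive inputs, are clamped
  to zero with the deficit moved to a sibling branch so path lengths are
  approximately preserved.
* **Genetic groups** are the connected components of the graph with an edge
  wherever ANI > 95% *and* AAI > 90% (strict inequalities). Connected
  components are the weakest aggregation rule consistent with pairwise
  thresholds; with the clean separation seen in these panels every
  reasonable rule coincides.

## The synthetic panel generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical shape of the study system:

* a panel of clades, each with a stem branch (`branch_in`, default 0.15
  expected proposals/site) and tip branches (`branch_within`, default
  0.01), giving within-clade nucleotide identity above 95% and
  between-clade identity near 85–92%;
* ~200–250 genes per genome averaging 150 codons (roughly 180–720 nt),
  ~91% coding density, AT-rich composition (overall GC around 25–30%);
* strong purifying selection: nonsynonymous proposals accepted with
  probability `omega` (default 0.1), synonymous always;
* clade-specific third-position composition via per-clade codon profiles.

Genes are drawn from a codon profile defined as a product of per-position
base distributions — first/second positions set by a `gc12_target`, third
positions by `gc3_target` and the two PR2 skews — conditioned on sense
codons. This construction was chosen over per-amino-acid sampling because
it keeps two properties simultaneously: at neutral targets
(0.5/0.5/0.5) within-family probabilities are exactly uniform, and the
expected GC3 of a long gene stays within ±0.02 of the target for any
admissible target (excluding the three stop codons perturbs third-position
weights by well under that; the profile constructor verifies the bound and
errors out naming the binding constraint if it ever fails).

Evolution is a codon-level rejection simulation: per-site nucleotide
proposals at rate `t` with HKY-style transition bias `kappa` (default 2)
and clade-specific proposal base frequencies; proposals creating stops are
rejected (the terminal stop may only exchange with another stop), and
nonsynonymous proposals are accepted with probability `omega`. Rejection
sampling was preferred over matrix-exponential simulation because it makes
the stop-codon exclusion exact and is entirely adequate at these
divergences. Intergenic spacers evolve neutrally at the same rates and are
drawn i.i.d. from the genes' background composition. A single RNG stream
seeded from the panel spec makes panels bit-reproducible.

What the generator does *not* emulate: indels, rearrangements, gene
gain/loss, recombination, and within-genome rate heterogeneity. Passing
tests therefore demonstrate correctness of the statistics and the recovery
machinery under a clean substitution-only model; they do not certify
behaviour on structurally rearranged genomes (the study system's
*Bemisia*-associated lineages are exactly such a case at the synteny level,
which is out of scope here).

A note on parameter recovery: the NG86 estimator recovers the simulator's
`omega` only approximately — with transition bias `kappa > 1`, NG86's
unweighted site counting is known to bias Ka/Ks slightly downward. At the
default conditions the panel's median Ka/Ks comes out near 0.075–0.08 for a
true acceptance ratio of 0.1, within the ±0.05 band the recovery checks
use. This is a property of the classical estimator, not a defect of the
simulator.

## Numerical and engineering choices

* Coordinates are 0-based half-open internally; GenBank's 1-based inclusive
  intervals are converted on input. Compound `join()` locations are
  supported only for origin-spanning features of circular genomes; other
  compound locations are dropped with a warning.
* Coding density is the fraction of the genome covered by the union of all
  annotated features (CDS and RNA genes, overlaps counted once) — the
  convention used for highly reduced genomes; a CDS-only density is
  reported alongside, since the term is used both ways.
* QC before codon statistics drops genes that are out of frame, shorter
  than 90 nt, contain ambiguous bases, or contain internal stops; every
  drop is logged with its reason.
* The pipeline writes a `manifest.json` with the configuration, a
  configuration hash and the MD5 of every output file; reruns with the same
  configuration are byte-identical, which the test suite verifies by
  hashing. Provenance lives in the manifest rather than inside the TSVs so
  the tables stay round-trip stable.
* Problem sizes in the test suite: most checks run on a 6-genome,
  30-gene-per-genome panel; the end-to-end recovery checks run once at the
  study's own scale (9 genomes, 200 genes). These sizes give stable
  statistics (recovery margins are wide at both scales) while keeping the
  default run fast.

## Known limitations

* ANI/AAI are ortholog-alignment based; expect small systematic offsets
  against fragment-mapping tools on real data.
* Orthogroup counts from MCL-based tools (OrthoFinder) are not reproduced
  exactly by RBH; the single-copy table is the supported product.
* The Ka/Ks estimator is fixed to NG86 + Jukes–Cantor; likelihood methods
  (GY94) and gamma corrections are out of scope.
* Bootstrap support values on the Mash NJ tree are not computed.
* The GenBank reader covers the flat-file dialect needed for these panels
  (single-record, simple and origin-spanning locations, `locus_tag`
  qualifiers); it is not a general-purpose GenBank parser.
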