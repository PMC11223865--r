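---
title: "Allele-specific PAM discovery: model, parameters and limitations"
author: "snvpam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific PAM discovery: model, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvpam)
```

## The problem and the model

A Cas nuclease engages DNA only next to its protospacer adjacent motif
(PAM). If a heterozygous single-nucleotide variant (SNV) creates a PAM on
the mutant allele that the wild-type allele lacks, cleavage can be
restricted to the mutant copy — the central requirement for treating
dominant disease by selective allele disruption. `snvpam` formalises this
as a matching problem over degenerate IUPAC patterns.

For a variant at position $p$ with reference base $r$ and mutant base
$m$, and a PAM pattern $P$ of length $L$, the **search window** is the
reference interval $[p-L,\, p+L]$ (clipped at contig ends, never padded):
every placement of $P$ that overlaps the variant lies fully inside it.
Pattern $P$ qualifies as an *SNV-derived PAM* iff

1. at least one placement of $P$, or of its reverse complement, matches
   the mutant window, and
2. **no** placement of $P$ or its reverse complement matches the
   wild-type window — at any offset, on either strand.

Clause 2 is deliberately evaluated over the whole window rather than only
at the mutant-matching offset. A wild-type match one base away would let
the enzyme load onto both alleles, defeating selectivity; the classic
failure case is the `NG` pattern on an N→G variant whose next base is
already a G. Whether an opposite-orientation wild-type match should also
disqualify is not settled by any first principle; we disqualify
(conservative), since a nuclease does not care which strand presented the
motif.

Two consequences of clause 2 are worth knowing. First, every emitted hit
necessarily overlaps the variant (a match away from the centre would be
identical in both alleles and thus excluded) — the package asserts this
emergent property in its tests rather than enforcing it. Second, a
pattern symbol `N` can never sit over the variant in a qualifying hit,
because it would match the wild-type base at the same placement.

### Ranking and the discrimination flag

Each pattern carries a **selectivity score**: the sum over symbols of a
specificity weight (N = 0.25; V, H, D, B = 0.33; M, R, W, S, Y, K = 0.50;
A, C, G, T = 1.00). The sum — rather than, say, the mean — is a package
design choice: it rewards both specificity and length, so the six-base
`NNGRRT` (3.50) outranks the two-base `TN` (1.25), matching the intuition
that a longer, more specific PAM requirement pins down more sequence
context. A mean-based score would treat `TTTT` and `T` as equals.

Hits whose aligned pattern symbol is a fully specific base equal to the
mutant nucleotide carry a discrimination flag (`*`): a C→G variant *can*
be admitted by an `R`, but an enzyme demanding a literal `G` there is the
safer choice. Ties in score break by this flag, then enzyme name, then
strand and offset — ordering is fully deterministic.

### The registry

The packaged registry (`inst/extdata/cas_registry.tsv`) holds 39 class-2
Cas enzymes — 22 natural, 17 engineered — with primary patterns,
less-preferred alternates and 39 PDB accessions. Less-preferred patterns
are stored separately and only searched on request
(`include_less_preferred = TRUE`), because they over-represent
targetability if treated as first-class. The converse risk — an enzyme
whose *alternate* pattern still matches the wild-type window — is handled
by `strict_promiscuity = TRUE`, which drops such enzymes entirely. One
transcription note: the source table's caption attributes two structures
to SaCas9-KKH while its body lists them under natural SaCas9; we follow
the body (totals are unaffected).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| contact `threshold` | 4.0 | Å | conventional heavy-atom contact cutoff at protein–DNA interfaces; the case-study contact set is defined at this radius |
| BLOSUM62 `threshold` | 0 | score | non-negative exchanges are the matrix's own notion of "conservative"; raising it monotonically shrinks candidate sets |
| `include_less_preferred` | FALSE | – | alternates are lower-affinity; opt-in |
| `strict_promiscuity` | FALSE | – | opt-in guard against wild-type cleavage through alternate patterns |
| window half-width | pattern length | nt | fixed by the model, not user-tunable |

## Structural companion protocol

`find_pam_contacts()` reports every protein residue with at least one
heavy atom within the threshold of any heavy atom of the user-designated
PAM nucleotides. Three numerical choices matter:

* **Heavy atoms only.** Deposited Cas structures vary in hydrogen
  content; including H would make the contact set depend on the
  depositor's refinement protocol.
* **User-designated PAM.** Which nucleotides *are* the PAM is an
  annotation of the complex (authors number them relative to the
  protospacer); it is not derivable from coordinates, so the package
  refuses to guess.
* **Altloc resolution.** One atom per (residue, atom name): highest
  occupancy wins, ties go to altloc `A`. Note that bio3d's readers drop
  non-`A` altlocs by default; the package reads with `rm.alt = FALSE` so
  this rule actually governs.

Candidate substitutions for contact residues are read off the BLOSUM62
row of the wild-type residue; identity is always excluded. Conservation
is attached as advice, never as a filter — a highly conserved contact
residue may be catalytically required, but that judgement is left to the
user.

### Conservation index

The package needs a 0–1 per-residue conservation measure from a
user-supplied alignment (homolog retrieval and alignment are out of
scope; any aligned FASTA works, e.g. from MAFFT or MUSCLE). We use a
normalised mean pairwise similarity: for column residues $a, b$,

$$ n(a,b) = \frac{s(a,b) - \min S}{\max\big(s(a,a),\, s(b,b)\big) - \min S} $$

with $s$ the BLOSUM62 score and $\min S = -4$ its global minimum; pairs
involving a gap or non-standard residue contribute 0, and the column
score is the mean over all sequence pairs. The per-pair denominator (the
larger self-score) is what makes a fully conserved column score exactly
1.0 regardless of residue identity — a global max would score an all-Ala
column 0.53. This is a deliberately simple approximation to
similarity-weighted conservation schemes in the CAMPO family: it does not
down-weight redundant sequences, so a profile computed from a heavily
biased alignment will overstate conservation.

### The ΔΔG scorer contract and iterative ranking

No energy engine is bundled, by design: published ΔΔG values for Cas–PAM
interfaces come from specialised force-field pipelines we make no claim
to reproduce. Instead the package fixes a contract — a deterministic
`function(structure, mutation)` returning one number, negative =
more favourable PAM interaction — and orchestrates it. Because several
design engines report only their single best mutant per run,
`iterative_rank()` mirrors that usage: score the pool, extract the most
negative candidate, re-score the remainder, repeat. For a pool-independent
scorer this provably reduces to a single sort (a property test checks it
against random mocks); for a pool-dependent scorer the extraction order
follows per-round minima. Failures on individual candidates leave them
unscored and ranked last rather than aborting the run. Ties break by
residue number, then amino acid — never by floating-point happenstance.

`table_scorer()` / `constant_scorer()` are the documented mocks;
`subprocess_scorer()` shows how to wire in an external executable
(structure path and mutation string in, one number out).

## Synthetic data: what it emulates, and what it does not

`generate_fixture_variants()` draws uniform A/C/G/T references and places
SNVs at 30-nt spacings (so no two search windows interact). With
`context_rules`, a fixed wild-type context is planted around each site —
e.g. `CTACC` with the central A mutated to G controls the entire 5-nt
`TG` search window, guaranteeing by construction that every variant
creates a mutant-private `TG`. `synthetic_pam_complex()` builds toy
complexes with residues at exact chosen distances from PAM atoms, giving
contact detection a controlled ground truth;
`cas12c2_pam_site_synthetic()` uses it to rebuild the *contact topology*
of the Cas12c2 PAM-recognition site (five annotated residues inside
4.0 Å, decoys outside). The shipped
`inst/extdata/cas12c2_pam_site_synthetic.pdb` is exactly that object and
is labelled synthetic; it validates the detection protocol, not the
deposited coordinates.

Uniform-random DNA is not genomic DNA: real sequence has GC skew, repeats
and mutation-class biases. One visible consequence: on ClinVar-scale real
variants the shortest-PAM enzyme Cas12c2 (`TN`) dominates coverage, but
on uniform-random windows `TN` rarely qualifies — its `N` matches a
quarter of all dinucleotides, so a wild-type window clean of `TN`/`NA` is
rare — and the 2-nt `TG` or 3-nt patterns top the ranking instead. The
package therefore asserts the robust qualitative form (short patterns
out-cover long ones; the top enzyme carries a ≤3-nt PAM) rather than any
percentage. Passing screens here demonstrate correct aggregation and
ranking machinery, not clinical targetability rates; the published
whole-ClinVar statistics (98.5% targetable, 47.1%/52.9% natural/engineered
split) depend on a specific ClinVar snapshot and are intentionally not
reproduced as numbers.

Problem sizes used in the shipped checks — 10^4 random window/pattern
pairs for matcher–oracle equivalence, screens of 150–250 variants,
toy structures of ≤40 atoms — were chosen as the smallest scales at which
every property is exercised with margin.

## Degenerate inputs and edge rules

* Windows are clipped at contig ends; placements must lie fully inside.
* Non-A/C/G/T reference characters inside a window disqualify any
  placement covering them (ambiguity cannot guarantee exclusivity) and
  raise a warning.
* Only single-base substitutions are accepted; indels/MNVs error out.
* VCF input is read permissively (headerless 5-column text parses);
  non-SNV rows are skipped and counted, never fatal.
* An empty candidate pool ranks to an empty table; an empty variant list
  screens to zero-count summaries.

## Known limitations

* Conservation scoring ignores sequence redundancy (see above).
* The ΔΔG layer orders candidates only as well as the scorer plugged into
  it; the mocks demonstrate orchestration, not energetics.
* Exclusivity is judged within the search window only; a PAM recreated by
  a *second* nearby variant on the wild-type haplotype is out of scope.
* The registry is a static snapshot with user extension; it does not sync
  to external Cas databases, and PAM preferences are patterns, not
  position-frequency models (affinity differences between a primary and a
  less-preferred PAM are not quantified).
* No ClinVar connectivity: cohort analyses require the user to export
  variants to VCF/HGVS first.
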