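# snvpam — allele-specific CRISPR targeting via SNV-derived PAMs

Dominantly inherited diseases call for disrupting the mutant allele while
leaving the wild-type copy intact. Guide-RNA mismatches alone rarely give
that selectivity, because Cas nucleases tolerate them. A more robust route
exploits the PAM (protospacer adjacent motif): when a single-nucleotide
variant (SNV) *creates* a PAM that the wild-type allele lacks, a Cas
enzyme requiring that PAM can only engage the mutant allele. `snvpam`
finds such **SNV-derived PAMs**, ranks the Cas enzymes that can use them,
and ships a structural companion protocol for engineering a Cas toward
stronger PAM selectivity.

The package is aimed at genome-editing researchers triaging candidate
variants (e.g. dominant keratin mutations in epidermolysis bullosa
simplex) and at Cas engineers exploring PAM-interface mutations.

## What it computes

**Search protocol.** For a variant with reference base centred in a window
that extends one pattern length up- and downstream, a degenerate IUPAC
pattern *P* qualifies as an SNV-derived PAM iff

* some placement of *P* (or its reverse complement) matches the mutant
  window, and
* no placement of *P* (or its reverse complement) matches the wild-type
  window anywhere.

The second clause is what makes flanking sequence matter: with the `NG`
pattern and an N→G variant followed by a G, `NG` can sit its `N` on the
wild-type base, so the pattern cuts both alleles and is rejected.

Qualifying enzymes are ordered by a **selectivity score** — the sum of
per-symbol specificity weights (N = 0.25; V/H/D/B = 0.33; M/R/W/S/Y/K =
0.50; A/C/G/T = 1.00), so `NNGRRT` scores 3.50 and `NG` only 1.25 — and hits
whose pattern aligns a fully specific base equal to the mutant nucleotide
carry a `*` discrimination flag.

The packaged registry covers 39 class-2 Cas enzymes (22 natural, 17
engineered) with their primary and less-preferred PAM patterns and 39 PDB
accessions; user enzymes can be appended.

**Structural protocol.** Given a Cas–DNA complex and the PAM nucleotides,
`find_pam_contacts()` lists every protein residue with a heavy atom within
a distance threshold (default 4.0 Å) of the PAM;
`contact_mutation_candidates()` proposes substitutions with non-negative
BLOSUM62 scores; `conservation_index()` annotates residues with a 0–1
alignment-based conservation index; and `iterative_rank()` orders
candidates by repeatedly extracting the best (most negative ΔΔG) mutant
under a pluggable, deterministic scorer.

## Worked example

An A→G variant inside a wild-type `TA` context (the situation of the
keratin-14 case variant `NG_008624.1:g.8631A>G`):

```r
library(snvpam)
hits <- find_snv_derived_pams("AACTACCAA", variant("KRT14_frag", 5, "A", "G"))
hits
#> SNV-derived PAM hits for KRT14_frag:g.5A>G
#>        enzyme pattern less_preferred strand offset matched_seq score
#>     Cas12c1 *      TG          FALSE      +     -1          TG  2.00
#>  FnCas9-RHA *      YG          FALSE      +     -1          TG  1.50
```

The mutant allele gains a `TG` dinucleotide that Cas12c1 requires; the
`*` marks that the aligned pattern symbol is a specific `G` equal to the
mutant base. Cas12c2 (`TN`) is absent: its `N` also matches the wild-type
`TA`, so it cannot distinguish the alleles — which is exactly why the
structural protocol asks whether Cas12c2 can be nudged toward `TG`:

```r
s  <- load_structure(system.file("extdata", "cas12c2_pam_site_synthetic.pdb",
                                 package = "snvpam"))
ct <- find_pam_contacts(s, pam_chain = "D", pam_resno = 7:8, threshold = 4.0)
ct$resno
#> [1] 137 289 291 294 351
ranked <- iterative_rank(contact_mutation_candidates(ct),
                         table_scorer(c(T291N = -1.0)), s)
head(ranked[, c("mutation", "blosum_score", "ddg", "rank")], 1)
#>   mutation blosum_score ddg rank
#> 1    T291N            0  -1    1
```

Five residues contact the PAM dinucleotide, and with a scorer favouring
T291N that substitution ranks first — the threonine→asparagine exchange
that distinguishes the TG-specific Cas12c1 pocket from Cas12c2's
promiscuous TN reading. (The shipped structure is a synthetic
reconstruction of the site's contact geometry, generated by
`cas12c2_pam_site_synthetic()`; use the deposited PDB entry 7V94 for real
structural work. No physics-based ΔΔG engine is bundled: `table_scorer()`
and `constant_scorer()` are deterministic mocks, and `subprocess_scorer()`
adapts any external per-mutation design tool.)

A shell interface wraps the same functions:

```sh
exec/snvpam find --fasta ref.fa --hgvs "g.5A>G" --out hits.tsv
exec/snvpam contacts --structure complex.pdb --pam-chain D --pam-residues 7,8
```

## Scope

The package performs no gRNA design, off-target scanning, editing-
efficiency prediction, or structure visualisation, and it does not talk to
ClinVar or other services: variants come in as VCF rows, HGVS-g strings or
position/ref/alt triplets, alignments as aligned FASTA, structures as
PDB/mmCIF files. See `vignettes/allele-specific-pam-discovery.Rmd` for the
model, parameter choices and limitations.
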