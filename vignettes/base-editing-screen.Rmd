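---
title: "Screening pathogenic SNVs for base-editing amenability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening pathogenic SNVs for base-editing amenability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescreen)
```

## The problem

CRISPR base editors correct single-nucleotide variants without double-strand
breaks: an adenine base editor (ABE) deaminates A to (effectively) G, a
cytosine base editor (CBE) converts C to T, and glycosylase editors (CGBE)
perform the C-to-G transversion. A pathogenic SNV is therapeutically
addressable when three conditions line up:

1. **Chemistry.** The substitution must be revertible by one of the available
   conversions. On double-stranded DNA that means the four transitions
   (G>A, C>T, A>G, T>C) and the two C:G<->G:C transversions; the mutant base
   (or its complement) must be the editor's substrate.
2. **Geometry.** A Cas protein must be able to bind next to the variant: a
   protospacer placement must exist that puts the mutant base inside the
   editor's *editing window* while the adjacent protospacer-adjacent motif
   (PAM) matches the Cas variant's recognition pattern.
3. **Safety.** Every other substrate base inside the editing window is a
   potential *bystander edit*. Its consequence — silent, missense, nonsense,
   or disruption of a canonical splice dinucleotide — determines whether the
   strategy is tolerable.

`bescreen` implements this three-stage screen as a small, fully testable
pipeline, motivated by inherited retinal degeneration caused by biallelic
*CRB1* variants: the bundled case fixtures reconstruct the loci of
c.2843G>A (p.Cys948Tyr), c.2833G>A (p.Gly945Arg) and c.2234C>T (p.Thr745Met),
three missense variants observed in patients with early-onset cone–rod
dystrophy. CRB1 is a natural target for base editing because its multiple
isoforms complicate conventional gene-replacement therapy.

## The transcript model

Guide placement is a *genomic* question (protospacers are contiguous in the
genome and happily run across exon–intron boundaries) while consequence
annotation is a *coding* question (codons are read across spliced junctions).
`mini_transcript` therefore models a genomic slice as ordered segments —
optional flank, exons alternating with introns, optional flank — and carries a
per-base coordinate map between the two views:

* exonic bases get contiguous HGVS c. coordinates from `cds_start`;
* intronic bases are addressed as `anchor+k` / `anchor-k` relative to the
  nearest exonic base, split at the intron midpoint (donor side `+`, acceptor
  side `-`), so `c.2843-2` is the acceptor-side adenine two bases upstream of
  exon start c.2843;
* introns must begin `gt` and end `ag` unless explicitly flagged
  non-canonical.

All sequence is stored uppercase in coding orientation; case in input or
output (lowercase introns, lowercase PAM) is typography, never data. The
reverse strand is computed on demand, which keeps a single source of truth and
makes strand handling testable.

**Flanks are not sequence.** The case loci are reconstructed from short
published context strings, so everything outside them is unknown. Flank
segments hold deterministic filler so windows have something to index into,
but any protospacer or PAM placement overlapping a flank is *skipped with a
warning*, never matched. This is load-bearing: filler is not real genome, and
counting a PAM match against it would manufacture guides that may not exist
at the real locus (e.g. an NGG "match" against the reverse complement of a
C-run). Users who want placements near a slice edge should model more real
sequence, not longer flanks.

**Incomplete codons.** A codon truncated by the slice edge is reported as
incomplete and skipped by consequence calls with a warning — short fixtures
must never be silently translated past their edges.

## The editor registry

Four ABE8e constructs are registered by default:

| construct | PAM | side | spacer | window |
|---|---|---|---|---|
| nSpCas9-ABE8e | NGG | 3' | 20 | 4–8 |
| nSaCas9-ABE8e | NNGRRT | 3' | 21 | 3–13 |
| KKH-nSaCas9-ABE8e | NNNRRT | 3' | 21 | 3–13 |
| CasMINI-ABE8e | TTTR | 5' | 20 | 3–8 |

PAM matching is positionwise over the IUPAC degeneracy sets and the PAM abuts
the protospacer directly (standard Cas geometry). Window positions are always
counted 1-based from the protospacer's 5' end on the targeted strand, for
5'-PAM constructs too; construct-specific windows absorb any offset.

The editing windows deserve a note. The deaminase windows of these constructs
are not crisp physical constants — they are activity profiles, and published
values vary with assay. The defaults here are the simplest intervals that are
internally consistent with the bundled case results: window 4–8 for SpCas9
(the classic high-activity core) and 3–13 for the SaCas9 scaffolds (wide, as
reported for ABE8e on SaCas9; exactly reproducing the four/three listed
bystanders while excluding the adenine at protospacer position 14 that both
Sa guides carry). They are plain configuration — `load_registry()` overrides
any field from a YAML/JSON file — and analyses that hinge on a window edge
should be rerun under perturbed windows. CasMINI's PAM and window are taken
from the Cas12f construct literature and flagged low-confidence in the
registry itself; no worked example constrains them.

## Stage 1: amenability

`classify_variant(ref, alt)` is a deterministic six-row table: G>A is
ABE/forward, C>T is ABE/reverse, A>G CBE/reverse, T>C CBE/forward, G>C
CGBE/forward, C>G CGBE/reverse; the other six substitutions return an empty
list. The table is exhaustively tested by simulating the conversion on the
mutant allele and projecting back to the coding strand, which must restore the
reference base in all twelve ordered pairs. CGBE is included for completeness
of the chemistry even though no bundled case uses it.

## Stage 2: guide enumeration

For each window position *p*, `enumerate_guides()` places the spacer so the
mutant base sits at *p* on the targeted strand, checks the adjacent PAM, and
emits a candidate if it matches. Enumeration targets the *mutant* sequence —
the editable substrate is the pathogenic allele; the wild type is only the
comparison point for consequences. Candidates are ordered by window
centrality, then 5'-most position: the source material reports a single guide
per construct without stating a selection rule, so the ordering is an explicit
artifact decision that at least prefers placements with the target deep in
the window.

The enumeration is cross-checked in the test suite against an independent
brute-force scanner that slides every protospacer+PAM placement over the
slice, and against planted ground truth: a generator writes a concrete PAM
next to a chosen placement and the pipeline must recover exactly it (100/100
seeded trials; 0/100 after the PAM is scrambled to violate its pattern).

## Stage 3: bystander analysis

Within a candidate's window, every substrate base other than the target is a
bystander. `annotate_edit()` projects the conversion to the coding strand
(reverse-strand A>G renders as T>C), renders the c. label, and classifies:

* intronic offset ±1/±2 — `canonical_splice` (splice-ablating);
* ±3…±8 — `splice_region` (an artifact convention; only the canonical band
  carries the "likely splicing variant" weight);
* deeper intronic and flank positions — `intronic`, reported rather than
  dropped so bystander counts are honest;
* exonic — wild-type vs edited codon: `silent`, `missense`, `nonsense`,
  `start_loss`.

Because a deaminase can convert any subset of the window's substrate bases,
`codon_outcomes()` groups editable positions by codon and translates all
2^k on/off combinations (k ≤ 3 in practice), reporting the distinct reachable
amino acids against the wild-type residue — the slash notation Q944Q/R.
Outcome labels order amino acids alphabetically; published orderings are
inconsistent, so tests compare outcome *sets*, never label strings. Codons
whose only editable base is the target are omitted (correcting the target is
the point, not a bystander), as are codons only reachable as wild type.
The combinatorial enumeration is oracle-tested against brute-force edits
applied to the full transcript.

`bystander_report()` additionally asserts that editing the target alone
restores the wild-type amino acid — the round-trip property that makes the
whole strategy meaningful.

## Synthetic data

The generator exists so every stage is testable without downloads, at the
conditions the case loci exhibit:

* `fixture_AB()` / `fixture_C()` reconstruct the case loci from the published
  context strings. Unknown filler is the letter "c" (upstream exon-A flank:
  "cag" repeats), chosen so the filler can complete neither the 3' PAMs
  (NGG/NNGRRT/NNNRRT) nor 5' TTTR at the inspected offsets; together with the
  flank-exclusion rule this pins the per-construct availability matrix to the
  published verdicts. The 23-nt intron between c.2842 and c.2843 is
  biologically implausibly short but fully determined by the printed donor
  (`gtagg…tagagt`) and acceptor (`…ttag`) context; it is a synthetic
  stand-in, not the real intron.
* `random_transcript()` draws seed-deterministic multi-exon transcripts
  (defaults: exons 60–120 nt, introns 30–60 nt, GC 0.4 — gene-scale realism
  is irrelevant here; what matters is junction density, so tests use several
  short exons) with canonical gt/ag junctions.
* `plant_amenable_variant()` installs a variant of a chosen class/strand and
  writes a concrete PAM so the target lands at a chosen window position; the
  expected guide is recorded constructively, never by running the code under
  test. `scramble_pam()` breaks the planted PAM minimally.

What the generator does *not* emulate: real splice-site strength, codon usage,
repeat structure, chromatin, or editing efficiency. Passing tests show the
*bookkeeping* — coordinates, strands, windows, combinatorics — is exact; they
say nothing about whether a guide will edit efficiently in cells.

## Numerical and design choices

* Coordinates are 1-based inclusive HGVS c. style throughout; intron offsets
  split at the midpoint (ties to the donor side).
* Degenerate inputs fail loudly with classed conditions
  (`bescreen_parse_error`, `bescreen_domain_error`, `bescreen_range_error`,
  `bescreen_validation_error`); nothing is coerced silently.
* Reports are deterministic: stable row ordering, no timestamps in the body;
  the registry travels as an md5 fingerprint in the metadata.
* Problem sizes in the test and acceptance runs — 50 random transcripts for
  scanner equivalence, 100 planted recoveries, 100–200 draws for the algebraic
  properties — were chosen as the point where every construct and strand
  combination is exercised several times; the experiments are cheap and the
  sizes can be raised freely.

## Known limitations

* No efficiency or specificity modeling: no Doench/CFD scores, no off-target
  search, no processivity model (each window base is independently
  edited-or-not, which is exactly the reading the slash notation implies).
* No full HGVS grammar: SNVs only, no duplications/delins, no UTR
  coordinates, no genome-build liftover.
* The splice-region band (±3…±8) is a reporting convention, not a splice
  strength prediction; use a dedicated splice model for those calls.
* Fixtures model slices, not genes; conclusions about constructs whose
  placements would extend beyond a slice are deliberately unavailable rather
  than guessed.
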