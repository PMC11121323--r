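# bescreen

In silico screening of pathogenic single-nucleotide variants for CRISPR
base-editing amenability.

## What it is for

Biallelic *CRB1* variants cause severe, early-onset retinal degeneration with
no approved therapy, and the gene's multiple isoforms make conventional AAV
gene replacement awkward — which puts DNA base editing, correcting the variant
in place, on the table. Deciding whether a given SNV is actually editable is a
three-part question, and `bescreen` answers all three for a variant on a small
transcript model:

1. **Chemistry** — is the substitution one an editor can revert? An adenine
   base editor (ABE) performs A→G, a cytosine base editor (CBE) C→T, a
   glycosylase editor (CGBE) C→G. On duplex DNA that covers the four
   transitions and the two C:G↔G:C transversions; `classify_variant()` maps
   each to an editor class and a targeted strand (a coding G>A variant reads
   as an editable A on the forward strand; C>T as an A on the reverse).
2. **Geometry** — does a protospacer placement exist that puts the mutant base
   at window position *p* (with window start ≤ *p* ≤ window end, counted from
   the protospacer 5′ end) while the adjacent PAM matches the Cas variant's
   IUPAC pattern (NGG for nSpCas9, NNGRRT for nSaCas9, NNNRRT for
   KKH-nSaCas9, TTTR 5′ for CasMINI)? `enumerate_guides()` enumerates every
   such placement, genomically contiguous, exon–intron boundaries included.
3. **Safety** — which other substrate bases sit in the editing window, and
   what would editing them do? `bystander_report()` renders each bystander as
   an HGVS c. change, classifies it (canonical splice at intron offsets ±1/±2,
   splice region ±3–8, intronic, silent / missense / nonsense), and
   `codon_outcomes()` translates all 2^k edit combinations per affected codon
   into the reachable amino-acid set (the Q944Q/R notation).

The transcript model (`mini_transcript`) is a junction-aware slice: exons with
contiguous HGVS c. coordinates, introns addressed by offset notation
(`c.2843-2`), canonical gt/ag junctions, and explicit flank filler that guide
placement refuses to match against. Three case loci are bundled as
reconstructed fixtures (`fixture_AB()`, `fixture_C()`): c.2843G>A
(p.Cys948Tyr), c.2833G>A (p.Gly945Arg), and c.2234C>T (p.Thr745Met).

## Worked example

Screen the c.2843G>A variant against the default ABE8e registry:

```r
library(bescreen)

fx <- fixture_AB()                                  # reconstructed case locus
sm <- screen_matrix(fx$transcript, fx$variants[[2]]) # c.2843G>A
sm
#> c.2843G>A -> ABE targeting the forward strand
#>   nSpCas9-ABE8e        0 guide(s)
#>   nSaCas9-ABE8e        0 guide(s)
#>   KKH-nSaCas9-ABE8e    1 guide(s): TTAGATATTGCAAATGCTGTT | tttaat
#>   CasMINI-ABE8e        0 guide(s)
```

The variant is a G>A transition, so an ABE targeting the forward strand can
revert it — but only the PAM-relaxed KKH-nSaCas9 construct finds a placement
(`tttaat` satisfies NNNRRT but not NNGRRT). Its bystander profile:

```r
g <- sm$best[["KKH-nSaCas9-ABE8e"]]
bystander_report(fx$transcript, g, get_construct("KKH-nSaCas9-ABE8e"),
                 fx$variants[[2]])
#> c.2843G>A (KKH-nSaCas9-ABE8e): 4 bystander edit(s)
#>   pos  3  c.2843-2A>G    canonical_splice
#>   pos  7  c.2845A>G      missense         p.Ile949Val
#>   pos 12  c.2850A>G      silent           p.Ala950Ala
#>   pos 13  c.2851A>G      missense         p.Asn951Asp
#>   codon outcomes: I949I/V, N951D/N
#>   target edit restores wild type: TRUE

format_guide_display(g, fx$variants[[2]], classify_variant("G", "A")[[1]])
#> TTAG[G>A]TATTGCAAATGCTGTTtttaat
```

Four adenines share the 3–13 editing window with the target: one sits in the
splice acceptor (editing it would very likely ablate splicing), two are
missense, one silent — the safety picture that makes this guide problematic
despite the available PAM. The display string shows the protospacer uppercase,
the target alleles bracketed on the targeted strand, and the PAM lowercase.

A shell entry point wraps the same pipeline
(`exec/bescreen screen --transcript model.yaml --variants variants.tsv`),
with `fixtures` and `simulate` subcommands for writing the bundled loci and
seeded planted test cases.

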