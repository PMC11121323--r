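#' Reconstructed two-exon case locus (c.2827-c.2865 slice)
#'
#' A mini-locus around the two compound-heterozygous missense variants
#' c.2833G>A (p.Gly945Arg) and c.2843G>A (p.Cys948Tyr), rebuilt from the
#' published guide/PAM context strings. The slice is in coding orientation
#' with the wild-type alleles installed:
#'
#' * exon A `CTTCAAGGATTTGAAT` (c.2827-c.2842; codon 943 starts at c.2827),
#' * a short intron `gtaggtagagt` + `cctcctcc` + `ttag` (canonical donor and
#'   acceptor; filler where the real intron is unknown is the letter c),
#' * exon B `GTATTGCAAATGCTGTTTTTAAT` (c.2843-c.2865).
#'
#' The intron sits between c.2842 and c.2843, as required by the reported
#' splice-site bystander c.2843-2A>G. Flanks (`cagcagcag` upstream, `cccccc`
#' downstream) are unmodeled filler and excluded from guide placement. The
#' intron length (23 nt) is biologically short but fully determined by the
#' printed donor-side (`gtagg...tagagt`) and acceptor-side (`...ttag`) guide
#' context; it is a synthetic stand-in, not the real intron.
#'
#' @return List with `transcript` (wild type) and `variants` (list of
#'   [be_variant()]: c.2833G>A, c.2843G>A).
#' @export
fixture_AB <- function() {
  t <- mini_transcript(
    list(
      list(kind = "flank", sequence = "cagcagcag"),
      list(kind = "exon", sequence = "CTTCAAGGATTTGAAT"),
      list(kind = "intron", sequence = paste0("gtaggtagagt", "cctcctcc", "ttag")),
      list(kind = "exon", sequence = "GTATTGCAAATGCTGTTTTTAAT"),
      list(kind = "flank", sequence = "cccccc")
    ),
    cds_start = 2827L,
    name = "fixture_AB"
  )
  list(transcript = t,
       variants = list(parse_variant("c.2833G>A"), parse_variant("c.2843G>A")))
}

#' Reconstructed single-exon case locus (c.2219-c.2241 slice)
#'
#' A mini-locus around the homozygous missense variant c.2234C>T
#' (p.Thr745Met), rebuilt as the reverse complement of the published
#' reverse-strand guide + PAM string. Wild-type coding-strand slice:
#' `CCATGTTTGTCCGAACGCTTCAA` (c.2219-c.2241), `cccccc` filler flanks on both
#' sides. Codons 740 and 747 are truncated at the slice edges and report as
#' incomplete.
#'
#' @return List with `transcript` (wild type) and `variants` (list with
#'   c.2234C>T).
#' @export
fixture_C <- function() {
  t <- mini_transcript(
    list(
      list(kind = "flank", sequence = "cccccc"),
      list(kind = "exon", sequence = "CCATGTTTGTCCGAACGCTTCAA"),
      list(kind = "flank", sequence = "cccccc")
    ),
    cds_start = 2219L,
    name = "fixture_C"
  )
  list(transcript = t, variants = list(parse_variant("c.2234C>T")))
}

#' All bundled case fixtures
#' @return Named list of fixture bundles (`fixture_AB`, `fixture_C`).
#' @export
case_fixtures <- function() {
  list(fixture_AB = fixture_AB(), fixture_C = fixture_C())
}
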