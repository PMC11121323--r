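# Independent oracles: deliberately use different mechanisms than the package
# paths they cross-check.

# reverse complement by character table + rev()
oracle_revcomp <- function(s) {
  chars <- strsplit(chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                           "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s),
                    "", fixed = TRUE)[[1]]
  paste(rev(chars), collapse = "")
}

# IUPAC matching via a regex built from the code map
oracle_iupac_match <- function(pattern, seq) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(toupper(pattern), "")[[1]]]
  rx <- paste0("^", paste(sprintf("[%s]", sets), collapse = ""), "$")
  grepl(rx, toupper(seq))
}

# Brute-force placement scanner: slides every protospacer start over the
# genomic slice on the strategy's strand, keeps placements whose PAM matches
# and whose protospacer holds the mutant base inside the editing window, and
# rejects anything touching flank filler or leaving the sequence. Returns a
# character set "strand/proto_start/window_pos" for comparison with
# enumerate_guides().
oracle_scan <- function(transcript, variant, construct, strategy) {
  cur <- get_base(transcript, variant$position)
  mt <- if (cur == variant$alt) transcript else
    apply_edit(transcript, variant$position, variant$alt)
  m <- mt$map
  gi <- if (variant$position$offset == 0L) {
    which(!is.na(m$cds) & m$cds == variant$position$base)
  } else {
    which(m$kind != "exon" & m$anchor == variant$position$base &
            m$offset == variant$position$offset)
  }
  stopifnot(length(gi) == 1L)
  N <- nchar(mt$seq)
  L <- construct$spacer_length
  P <- nchar(construct$pam)
  ws <- construct$window[["start"]]; we <- construct$window[["end"]]
  hits <- character(0)
  for (a in seq_len(N)) {
    b <- a + L - 1L
    if (b > N) break
    if (gi < a || gi > b) next
    if (strategy$target_strand == "forward") {
      p <- gi - a + 1L
      proto <- substr(mt$seq, a, b)
      pam_rng <- if (construct$pam_side == "3prime") c(b + 1L, b + P) else
        c(a - P, a - 1L)
      pam <- if (pam_rng[1] >= 1L && pam_rng[2] <= N)
        substr(mt$seq, pam_rng[1], pam_rng[2]) else NA
    } else {
      p <- b - gi + 1L
      proto <- oracle_revcomp(substr(mt$seq, a, b))
      pam_rng <- if (construct$pam_side == "3prime") c(a - P, a - 1L) else
        c(b + 1L, b + P)
      pam <- if (pam_rng[1] >= 1L && pam_rng[2] <= N)
        oracle_revcomp(substr(mt$seq, pam_rng[1], pam_rng[2])) else NA
    }
    if (is.na(pam)) next
    if (p < ws || p > we) next
    if (substr(proto, p, p) != strategy$mutant_base_on_target_strand) next
    touched <- min(a, pam_rng[1]):max(b, pam_rng[2])
    if (any(m$kind[touched] == "flank")) next
    if (!oracle_iupac_match(construct$pam, pam)) next
    hits <- c(hits, paste(strategy$target_strand, a, p, sep = "/"))
  }
  sort(hits)
}

# key set of enumerate_guides() output in the oracle's format
guide_keys <- function(guides) {
  sort(vapply(guides, function(g) {
    paste(g$strand, min(g$proto_range), g$target_window_position, sep = "/")
  }, ""))
}

# brute-force codon outcome set: apply every on/off combination of the given
# window edits to the full transcript and read off the translated codon
oracle_codon_outcomes <- function(transcript, guide, construct, positions,
                                  codon_index) {
  proj_alt <- if (guide$strand == "forward") construct$conversion[["to"]] else
    chartr("ACGT", "TGCA", construct$conversion[["to"]])
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(positions)))
  aas <- apply(combos, 1L, function(onoff) {
    t2 <- transcript
    for (p in positions[onoff]) {
      row <- guide$span[guide$span$proto_pos == p, ]
      t2 <- apply_edit(t2, coding_position(row$anchor, row$offset), proj_alt)
    }
    codon_sequence(t2, codon_index)$aa
  })
  sort(unique(aas))
}

# convenience: strategy + guides for a fixture variant/construct
fixture_guides <- function(bundle, variant_idx, construct_name) {
  v <- bundle$variants[[variant_idx]]
  strategy <- classify_variant(v$ref, v$alt)[[1]]
  construct <- get_construct(construct_name)
  guides <- suppressWarnings(
    enumerate_guides(bundle$transcript, v, construct, strategy))
  list(variant = v, strategy = strategy, construct = construct, guides = guides)
}
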