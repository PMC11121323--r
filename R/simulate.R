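#' Random junction-bearing transcript
#'
#' Seed-deterministic generator of a multi-exon mini-transcript with canonical
#' gt/ag dinucleotides at every junction and small flank filler segments.
#' Base composition is i.i.d. with the requested GC content.
#'
#' @param n_exons Number of exons (>= 1; `1` yields no introns).
#' @param exon_len_range,intron_len_range Integer ranges `c(min, max)`;
#'   introns must allow at least 4 nt (gt + ag).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same transcript.
#' @param cds_start CDS coordinate of the first exonic base.
#' @param flank_len Length of the two flank filler segments (0 for none).
#' @return A [mini_transcript()].
#' @export
random_transcript <- function(n_exons, exon_len_range = c(60L, 120L),
                              intron_len_range = c(30L, 60L), gc = 0.4,
                              seed = 1L, cds_start = 1L, flank_len = 8L) {
  n_exons <- as.integer(n_exons)
  exon_len_range <- as.integer(exon_len_range)
  intron_len_range <- as.integer(intron_len_range)
  if (is.na(n_exons) || n_exons < 1L ||
      length(exon_len_range) != 2L || exon_len_range[1] < 1L ||
      exon_len_range[1] > exon_len_range[2] ||
      length(intron_len_range) != 2L || intron_len_range[1] < 4L ||
      intron_len_range[1] > intron_len_range[2] ||
      !is.numeric(gc) || gc <= 0 || gc >= 1) {
    be_stop("invalid generator parameters", "bescreen_domain_error")
  }
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_seq <- function(n) {
      if (n == 0L) return("")
      paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
    }
    segs <- list()
    if (flank_len > 0L) {
      segs[[length(segs) + 1L]] <- list(kind = "flank",
                                        sequence = rand_seq(flank_len))
    }
    for (i in seq_len(n_exons)) {
      segs[[length(segs) + 1L]] <- list(
        kind = "exon",
        sequence = rand_seq(sample(exon_len_range[1]:exon_len_range[2], 1L)))
      if (i < n_exons) {
        L <- sample(intron_len_range[1]:intron_len_range[2], 1L)
        segs[[length(segs) + 1L]] <- list(
          kind = "intron",
          sequence = paste0("GT", rand_seq(L - 4L), "AG"))
      }
    }
    if (flank_len > 0L) {
      segs[[length(segs) + 1L]] <- list(kind = "flank",
                                        sequence = rand_seq(flank_len))
    }
    mini_transcript(segs, cds_start = cds_start,
                    name = sprintf("sim_seed%d", as.integer(seed)))
  })
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# (class, strand) -> the unique coding-strand substitution it reverts.
substitution_for <- function(editor_class, strand) {
  key <- vapply(names(AMENABLE_TABLE), function(k) {
    e <- AMENABLE_TABLE[[k]]
    e$editor_class == editor_class && e$target_strand == strand
  }, TRUE)
  k <- names(AMENABLE_TABLE)[key]
  stopifnot(length(k) == 1L)
  list(ref = substr(k, 1, 1), alt = substr(k, 3, 3))
}

#' Plant an amenable variant with a constructed PAM
#'
#' Selects an exonic position, installs the wild-type allele of a substitution
#' amenable to `strategy_class` on `strand`, and overwrites the sequence
#' adjacent to the chosen protospacer placement with a concrete PAM drawn from
#' the construct's pattern, so that the mutant base sits at `window_position`
#' of the protospacer. The expected guide is recorded constructively at
#' planting time, not by running the enumeration under test. Placements that
#' would overwrite flank filler or an intron's splice dinucleotides are
#' rejected and re-drawn.
#'
#' @param transcript A [mini_transcript()] with room for protospacer + PAM.
#' @param construct Target [editor_construct()].
#' @param strategy_class `"ABE"`, `"CBE"` or `"CGBE"`.
#' @param seed Integer seed (drives all choices).
#' @param strand Optional fixed strand (`"forward"`/`"reverse"`); sampled if
#'   `NULL`.
#' @param window_position Optional fixed target window position; sampled from
#'   the construct's window if `NULL`.
#' @param max_tries Positions to try before giving up.
#' @return A `planted_case`: list with `transcript` (wild type + planted PAM),
#'   `variant`, `expected_strategy`, `expected` (construct, strand,
#'   target_window_position, proto_range, pam_range), `expected_none`
#'   (`FALSE`), `seed`.
#' @export
plant_amenable_variant <- function(transcript, construct,
                                   strategy_class = c("ABE", "CBE", "CGBE"),
                                   seed = 1L, strand = NULL,
                                   window_position = NULL, max_tries = 500L) {
  stopifnot(inherits(transcript, "mini_transcript"),
            inherits(construct, "editor_construct"))
  strategy_class <- match.arg(strategy_class)
  with_seed(seed, {
    strand <- if (is.null(strand)) sample(c("forward", "reverse"), 1L) else
      match.arg(strand, c("forward", "reverse"))
    p <- if (is.null(window_position)) {
      sample(construct$window[["start"]]:construct$window[["end"]], 1L)
    } else as.integer(window_position)
    if (p < construct$window[["start"]] || p > construct$window[["end"]]) {
      be_stop("window_position outside the construct's editing window",
              "bescreen_domain_error")
    }
    sub <- substitution_for(strategy_class, strand)
    L <- construct$spacer_length
    P <- nchar(construct$pam)
    m <- transcript$map
    exonic <- which(m$kind == "exon")
    if (length(exonic) == 0L) {
      be_stop("transcript has no exonic positions", "bescreen_domain_error")
    }
    # splice dinucleotides that must not be overwritten
    frozen <- unlist(lapply(unique(m$segment[m$kind == "intron"]), function(s) {
      idx <- which(m$segment == s)
      c(idx[1:2], idx[(length(idx) - 1):length(idx)])
    }))

    tries <- sample(exonic, min(max_tries, length(exonic)))
    for (gi in tries) {
      if (strand == "forward") {
        proto <- c(gi - (p - 1L), gi + (L - p))
        pam <- if (construct$pam_side == "3prime")
          c(proto[2] + 1L, proto[2] + P) else c(proto[1] - P, proto[1] - 1L)
      } else {
        proto <- c(gi - (L - p), gi + (p - 1L))
        pam <- if (construct$pam_side == "3prime")
          c(proto[1] - P, proto[1] - 1L) else c(proto[2] + 1L, proto[2] + P)
      }
      lo <- min(proto[1], pam[1]); hi <- max(proto[2], pam[2])
      if (lo < 1L || hi > nchar(transcript$seq)) next
      if (any(m$kind[lo:hi] == "flank")) next
      if (any(pam[1]:pam[2] %in% frozen)) next

      # install the wild-type ref allele at the target
      pos <- coding_position(m$cds[gi], 0L)
      t2 <- apply_edit(transcript, pos, sub$ref)
      # write a concrete PAM drawn from the pattern (targeted strand)
      pam_concrete <- sample_concrete_pam(construct$pam)
      t2 <- write_strand_seq(t2, pam[1]:pam[2], pam_concrete, strand)
      variant <- be_variant(pos, sub$ref, sub$alt)
      strategy <- classify_variant(sub$ref, sub$alt)[[1]]
      return(structure(
        list(transcript = t2, variant = variant,
             expected_strategy = strategy,
             expected = list(construct = construct$name, strand = strand,
                             target_window_position = p,
                             proto_range = proto, pam_range = pam,
                             pam_seq = pam_concrete),
             expected_none = FALSE, seed = as.integer(seed)),
        class = "planted_case"
      ))
    }
    be_stop("no exonic position with room for protospacer + PAM",
            "bescreen_domain_error")
  })
}

# Sample one concrete ACGT realisation of an IUPAC pattern.
sample_concrete_pam <- function(pattern) {
  letters <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(letters, function(l) {
    set <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "", fixed = TRUE)[[1]]
    sample(set, 1L)
  }, ""), collapse = "")
}

# Write `seq` (read 5'->3' on `strand`) into forward genomic positions `range`.
write_strand_seq <- function(t, range, seq, strand) {
  fwd <- if (strand == "forward") toupper(seq) else revcomp(seq)
  chars <- strsplit(fwd, "", fixed = TRUE)[[1]]
  stopifnot(length(chars) == length(range))
  for (i in seq_along(range)) {
    pos <- coding_position(t$map$anchor[range[i]], t$map$offset[range[i]])
    t <- apply_edit(t, pos, chars[i])
  }
  t
}

#' Scramble the planted PAM of a case
#'
#' Replaces one constrained position of the planted PAM with a base outside
#' its pattern letter's allowed set, so the placement no longer matches, and
#' marks the case `expected_none`.
#'
#' @param case A `planted_case` from [plant_amenable_variant()].
#' @param construct The [editor_construct()] the case was planted for.
#' @return The modified `planted_case` with `expected_none = TRUE`.
#' @export
scramble_pam <- function(case, construct) {
  stopifnot(inherits(case, "planted_case"),
            inherits(construct, "editor_construct"))
  letters <- strsplit(construct$pam, "", fixed = TRUE)[[1]]
  sizes <- vapply(letters, function(l) nchar(Biostrings::IUPAC_CODE_MAP[[l]]), 0L)
  if (all(sizes == 4L)) {
    be_stop("an all-N PAM cannot be scrambled", "bescreen_domain_error")
  }
  i <- which.min(sizes)
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[letters[i]]], "", fixed = TRUE)[[1]]
  bad <- setdiff(DNA_BASES, allowed)[1]
  scrambled <- case$expected$pam_seq
  substr(scrambled, i, i) <- bad
  range <- case$expected$pam_range[1]:case$expected$pam_range[2]
  case$transcript <- write_strand_seq(case$transcript, range, scrambled,
                                      case$expected$strand)
  case$expected$pam_seq <- scrambled
  case$expected_none <- TRUE
  case
}

#' Does enumeration recover a planted case?
#'
#' Convenience check used by the recovery experiments: runs
#' [enumerate_guides()] on the case and reports whether a candidate matches
#' the constructively recorded placement (same strand, window position and
#' PAM location).
#'
#' @param case A `planted_case`.
#' @param construct The [editor_construct()] it was planted for.
#' @return `TRUE` if the planted placement is found.
#' @export
recovers_planted <- function(case, construct) {
  g <- suppressWarnings(enumerate_guides(case$transcript, case$variant,
                                         construct, case$expected_strategy))
  any(vapply(g, function(x) {
    x$strand == case$expected$strand &&
      x$target_window_position == case$expected$target_window_position &&
      identical(as.integer(x$pam_range), as.integer(case$expected$pam_range))
  }, TRUE))
}
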