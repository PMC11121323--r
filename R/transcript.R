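#' Junction-aware mini-transcript model
#'
#' A `mini_transcript` models a contiguous genomic slice of a coding
#' transcript as an ordered list of segments (optional 5' flank, then exons
#' alternating with introns, then optional 3' flank), stored in coding
#' orientation. Exonic bases carry contiguous HGVS c. coordinates starting at
#' `cds_start`; intronic bases are addressed by the nearest exonic coordinate
#' plus a signed offset (`c.2843-2` is two bases into the intron upstream of
#' c.2843). Flank segments are unmodeled filler context: they carry no trusted
#' sequence identity and are excluded from guide placement.
#'
#' Sequence case is presentation-only: everything is normalised to uppercase
#' internally and no computation depends on input case.
#'
#' @param segments List of segments, each a `list(kind=, sequence=)` with kind
#'   one of `"exon"`, `"intron"`, `"flank"`.
#' @param cds_start CDS c. coordinate (integer >= 1) of the first exonic base.
#' @param name Transcript name.
#' @param strict_splice Require every intron to start `gt` and end `ag`
#'   (canonical donor/acceptor). Set `FALSE` only for deliberately
#'   non-canonical models.
#' @return An object of class `mini_transcript`.
#' @examples
#' t <- mini_transcript(
#'   list(list(kind = "exon", sequence = "ATGAAA"),
#'        list(kind = "intron", sequence = "gtcctag"),
#'        list(kind = "exon", sequence = "TTTGGG")),
#'   cds_start = 1, name = "toy")
#' get_base(t, 4)
#' @export
mini_transcript <- function(segments, cds_start, name = "transcript",
                            strict_splice = TRUE) {
  if (!is.list(segments) || length(segments) == 0L) {
    be_stop("segments must be a non-empty list", "bescreen_domain_error")
  }
  kinds <- vapply(segments, function(s) as.character(s$kind), "")
  seqs <- toupper(vapply(segments, function(s) as.character(s$sequence), ""))
  if (any(!kinds %in% c("exon", "intron", "flank"))) {
    be_stop("segment kind must be exon, intron or flank", "bescreen_domain_error")
  }
  if (any(!grepl("^[ACGT]+$", seqs))) {
    be_stop("segment sequences must be non-empty and over {A,C,G,T}",
            "bescreen_parse_error")
  }
  cds_start <- as.integer(cds_start)
  if (is.na(cds_start) || cds_start < 1L) {
    be_stop("cds_start must be an integer >= 1", "bescreen_domain_error")
  }

  # flanks only at the two ends; core alternates exon/intron, bounded by exons
  fl <- which(kinds == "flank")
  if (length(fl) > 0 && !all(fl %in% c(1L, length(kinds)))) {
    be_stop("flank segments are only allowed at the two ends",
            "bescreen_domain_error")
  }
  core <- kinds[kinds != "flank"]
  if (length(core) == 0L || core[1] != "exon" || core[length(core)] != "exon") {
    be_stop("the modeled slice must start and end with an exon segment",
            "bescreen_domain_error")
  }
  if (length(core) > 1 && any(core[-1] == core[-length(core)])) {
    be_stop("exon segments must alternate with intron segments",
            "bescreen_domain_error")
  }
  if (strict_splice) {
    for (i in which(kinds == "intron")) {
      s <- seqs[i]
      if (nchar(s) < 4L || substr(s, 1, 2) != "GT" ||
          substr(s, nchar(s) - 1, nchar(s)) != "AG") {
        be_stop(sprintf(
          "intron segment %d lacks canonical gt...ag splice dinucleotides", i),
          "bescreen_domain_error")
      }
    }
  }

  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L

  # first pass: contiguous cds coordinates across exons
  exon_first <- exon_last <- rep(NA_integer_, length(segments))
  nxt <- cds_start
  for (i in seq_along(segments)) {
    if (kinds[i] == "exon") {
      exon_first[i] <- nxt
      exon_last[i] <- nxt + lens[i] - 1L
      nxt <- exon_last[i] + 1L
    }
  }

  # second pass: per-base coordinate map
  n <- sum(lens)
  map <- data.frame(
    genomic = seq_len(n),
    base = strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]],
    kind = rep(kinds, lens),
    segment = rep(seq_along(segments), lens),
    cds = NA_integer_,
    anchor = NA_integer_,
    offset = NA_integer_,
    stringsAsFactors = FALSE
  )
  first_exon <- which(kinds == "exon")[1]
  last_exon <- max(which(kinds == "exon"))
  for (i in seq_along(segments)) {
    idx <- starts[i]:ends[i]
    j <- seq_len(lens[i])
    if (kinds[i] == "exon") {
      cds <- exon_first[i]:exon_last[i]
      map$cds[idx] <- cds
      map$anchor[idx] <- cds
      map$offset[idx] <- 0L
    } else if (kinds[i] == "intron") {
      prev_exon <- max(which(kinds[seq_len(i - 1)] == "exon"))
      prev_last <- exon_last[prev_exon]
      next_first <- prev_last + 1L
      L <- lens[i]
      donor <- j <= ceiling(L / 2)
      map$anchor[idx] <- ifelse(donor, prev_last, next_first)
      map$offset[idx] <- ifelse(donor, j, -(L - j + 1L))
    } else { # flank
      if (i == 1L) {
        map$anchor[idx] <- exon_first[first_exon]
        map$offset[idx] <- -(lens[i] - j + 1L)
      } else {
        map$anchor[idx] <- exon_last[last_exon]
        map$offset[idx] <- j
      }
    }
  }

  structure(
    list(
      name = as.character(name),
      segments = unname(Map(function(k, s) list(kind = k, sequence = s),
                            kinds, seqs)),
      cds_start = cds_start,
      seq = paste(seqs, collapse = ""),
      map = map
    ),
    class = "mini_transcript"
  )
}

#' @export
print.mini_transcript <- function(x, ...) {
  kinds <- vapply(x$segments, `[[`, "", "kind")
  lens <- vapply(x$segments, function(s) nchar(s$sequence), 0L)
  exonic <- x$map$kind == "exon"
  cat(sprintf("mini_transcript %s: %d segment(s), %d nt (%d exonic, c.%d-c.%d)\n",
              dQuote(x$name), length(kinds), nchar(x$seq), sum(exonic),
              min(x$map$cds, na.rm = TRUE), max(x$map$cds, na.rm = TRUE)))
  cat(paste(sprintf("  %s[%d]", kinds, lens), collapse = " "), "\n")
  invisible(x)
}

#' Parse an HGVS-style coding position
#'
#' Accepts `"2843"`, `"2843-2"`, `"100+1"`, with or without a leading `"c."`.
#'
#' @param text Position string.
#' @return A `coding_position`: list with integer fields `base` and `offset`
#'   (`offset == 0` iff exonic).
#' @examples
#' parse_c_position("2843-2")
#' @export
parse_c_position <- function(text) {
  assert_string1(text, "text")
  s <- sub("^c\\.", "", trimws(text))
  m <- regmatches(s, regexec("^(\\d+)([+-]\\d+)?$", s))[[1]]
  if (length(m) == 0L) {
    be_stop(sprintf("malformed coding position %s", dQuote(text)),
            "bescreen_parse_error")
  }
  base <- as.integer(m[2])
  offset <- if (m[3] == "") 0L else as.integer(m[3])
  if (base < 1L) {
    be_stop("coding position base must be >= 1", "bescreen_domain_error")
  }
  coding_position(base, offset)
}

#' Construct a coding position
#' @param base CDS coordinate, integer >= 1.
#' @param offset Intron offset (0 for exonic positions).
#' @return A `coding_position` object.
#' @export
coding_position <- function(base, offset = 0L) {
  base <- as.integer(base)
  offset <- as.integer(offset)
  if (is.na(base) || base < 1L || is.na(offset)) {
    be_stop("invalid coding position", "bescreen_domain_error")
  }
  structure(list(base = base, offset = offset), class = "coding_position")
}

#' Render a coding position in HGVS c. style (without the "c." prefix)
#' @param pos A `coding_position`, integer, or parsable string.
#' @return Character, e.g. `"2843"` or `"2843-2"`.
#' @export
format_c_position <- function(pos) {
  p <- as_coding_position(pos)
  if (p$offset == 0L) {
    as.character(p$base)
  } else {
    sprintf("%d%s%d", p$base, if (p$offset > 0) "+" else "-", abs(p$offset))
  }
}

#' @export
print.coding_position <- function(x, ...) {
  cat("c.", format_c_position(x), "\n", sep = "")
  invisible(x)
}

#' Coerce to a coding position
#' @param x A `coding_position`, a single integer (exonic), or a string.
#' @return A `coding_position`.
#' @export
as_coding_position <- function(x) {
  if (inherits(x, "coding_position")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(coding_position(x, 0L))
  if (is.character(x)) return(parse_c_position(x))
  be_stop("cannot interpret value as a coding position", "bescreen_domain_error")
}

#' Codon index and frame of a CDS position
#'
#' @param pos Exonic CDS coordinate (integer >= 1).
#' @return List with `index` (`ceiling(pos/3)`) and `frame` (1-3, position of
#'   the base within its codon).
#' @examples
#' c_to_codon(2843) # codon 948, frame 2
#' @export
c_to_codon <- function(pos) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) {
    be_stop("CDS position must be an integer >= 1", "bescreen_domain_error")
  }
  list(index = as.integer(ceiling(pos / 3)),
       frame = as.integer((pos - 1L) %% 3L + 1L))
}

#' CDS span of a codon
#' @param index Codon index (integer >= 1).
#' @return Integer vector of the three CDS coordinates of the codon.
#' @export
codon_span <- function(index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L) {
    be_stop("codon index must be an integer >= 1", "bescreen_domain_error")
  }
  (3L * index - 2L):(3L * index)
}

# Resolve a coding position to the genomic index within the modeled slice.
resolve_position <- function(t, pos) {
  p <- as_coding_position(pos)
  m <- t$map
  if (p$offset == 0L) {
    idx <- which(!is.na(m$cds) & m$cds == p$base)
  } else {
    idx <- which(m$kind != "exon" & m$anchor == p$base & m$offset == p$offset)
  }
  if (length(idx) != 1L) {
    be_stop(sprintf("position c.%s is outside the modeled region of %s",
                    format_c_position(p), dQuote(t$name)),
            "bescreen_range_error")
  }
  idx
}

# Render the c.-style label of a map row (flank rows use offset notation too,
# but their kind marks them as unmodeled filler).
render_map_label <- function(map_rows) {
  ifelse(map_rows$offset == 0L,
         as.character(map_rows$cds),
         sprintf("%d%s%d", map_rows$anchor,
                 ifelse(map_rows$offset > 0, "+", "-"),
                 abs(map_rows$offset)))
}

# coding_position of a map row
row_coding_position <- function(map_row) {
  coding_position(map_row$anchor, map_row$offset)
}

#' Read the coding-orientation base at a position
#' @param t A `mini_transcript`.
#' @param pos A coding position (object, integer, or string).
#' @return Single uppercase base.
#' @export
get_base <- function(t, pos) {
  stopifnot(inherits(t, "mini_transcript"))
  t$map$base[resolve_position(t, pos)]
}

#' Return a copy of the transcript with one base changed
#'
#' Single-base in-silico edit; no re-validation of splice dinucleotides is
#' performed (editing a splice site is exactly what bystander analysis needs
#' to represent).
#'
#' @inheritParams get_base
#' @param new_base Replacement base (A/C/G/T, case-insensitive).
#' @return A new `mini_transcript`.
#' @export
apply_edit <- function(t, pos, new_base) {
  stopifnot(inherits(t, "mini_transcript"))
  b <- toupper(new_base)
  if (!is.character(b) || length(b) != 1L || !b %in% DNA_BASES) {
    be_stop("new_base must be one of A, C, G, T", "bescreen_domain_error")
  }
  idx <- resolve_position(t, pos)
  seg <- t$map$segment[idx]
  seg_start <- idx - sum(t$map$segment < seg)
  out <- t
  substr(out$segments[[seg]]$sequence, seg_start, seg_start) <- b
  substr(out$seq, idx, idx) <- b
  out$map$base[idx] <- b
  out
}

#' Contiguous genomic-order window around a position
#'
#' Returns the forward (coding-orientation) sequence of the genomically
#' contiguous window `[center - left, center + right]`, together with a
#' per-base coordinate map. Windows may run from exon into intron (protospacer
#' placements are genomically, not spliced, contiguous). A window with
#' `left + right < 0` is empty.
#'
#' @inheritParams get_base
#' @param center Coding position at the window center.
#' @param left,right Number of bases to include left/right of the center.
#' @return List with `sequence` (string) and `map` (data.frame with genomic
#'   index, base, kind, and c.-style `label` per position).
#' @export
genomic_window <- function(t, center, left, right) {
  stopifnot(inherits(t, "mini_transcript"))
  left <- as.integer(left); right <- as.integer(right)
  gi <- resolve_position(t, center)
  lo <- gi - left
  hi <- gi + right
  if (hi < lo) {
    return(list(sequence = "",
                map = cbind(t$map[0, ], label = character(0))))
  }
  if (lo < 1L || hi > nchar(t$seq)) {
    be_stop("window exceeds the modeled sequence (including flanks)",
            "bescreen_range_error")
  }
  rows <- t$map[lo:hi, , drop = FALSE]
  rows$label <- render_map_label(rows)
  rownames(rows) <- NULL
  list(sequence = substr(t$seq, lo, hi), map = rows)
}

#' Extract a codon from the transcript, crossing junctions
#'
#' The three bases are read in coding order across exon-exon junctions. If
#' some (but not all) bases of the codon fall outside the modeled slice the
#' codon is returned as incomplete and is not translated.
#'
#' @param t A `mini_transcript`.
#' @param codon_index Codon index (1-based).
#' @return A `codon_ref`: list with `index`, `bases` (3-character string, or
#'   `NA` if incomplete), `complete`, `aa` (one-letter), `aa3` (three-letter).
#' @export
codon_sequence <- function(t, codon_index) {
  stopifnot(inherits(t, "mini_transcript"))
  span <- codon_span(codon_index)
  hits <- match(span, t$map$cds)
  if (all(is.na(hits))) {
    be_stop(sprintf("codon %d lies entirely outside the modeled slice",
                    as.integer(codon_index)), "bescreen_range_error")
  }
  complete <- !anyNA(hits)
  bases <- if (complete) paste(t$map$base[hits], collapse = "") else NA_character_
  aa <- if (complete) translate_codon(bases) else NA_character_
  structure(
    list(index = as.integer(codon_index), bases = bases, complete = complete,
         aa = aa, aa3 = if (complete) aa_three(aa) else NA_character_),
    class = "codon_ref"
  )
}

#' @export
print.codon_ref <- function(x, ...) {
  if (x$complete) {
    cat(sprintf("codon %d: %s (%s/%s)\n", x$index, x$bases, x$aa, x$aa3))
  } else {
    cat(sprintf("codon %d: incomplete in modeled slice\n", x$index))
  }
  invisible(x)
}

#' Serialize / read a transcript model
#'
#' The on-disk form is a plain YAML or JSON document: `name`,
#' `cds_start`, and ordered `segments` with `kind` + `sequence`. Intron and
#' flank sequences are written lowercase for readability (presentation only).
#'
#' @param t A `mini_transcript`.
#' @param path Output file; format inferred from the extension
#'   (`.yaml`/`.yml`/`.json`) unless given.
#' @param format `"yaml"` or `"json"`.
#' @return `write_transcript` returns `path` invisibly; `read_transcript`
#'   returns a `mini_transcript`.
#' @export
write_transcript <- function(t, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(t, "mini_transcript"))
  format <- match.arg(format)
  if (format == "auto") format <- infer_format(path)
  doc <- list(
    name = t$name,
    cds_start = t$cds_start,
    segments = lapply(t$segments, function(s) {
      list(kind = s$kind,
           sequence = if (s$kind == "exon") s$sequence else tolower(s$sequence))
    })
  )
  if (format == "yaml") {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- infer_format(path)
  doc <- if (format == "yaml") yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$segments) || is.null(doc$cds_start)) {
    be_stop(sprintf("transcript file %s lacks segments or cds_start",
                    dQuote(path)), "bescreen_validation_error")
  }
  mini_transcript(doc$segments, cds_start = doc$cds_start,
                  name = if (is.null(doc$name)) "transcript" else doc$name)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else be_stop(sprintf("cannot infer format from extension of %s", dQuote(path)),
               "bescreen_validation_error")
}

#' Import a single-exon transcript from a FASTA file
#'
#' Convenience importer for a contiguous exonic slice: the first FASTA record
#' becomes one exon segment with the declared `cds_start`.
#'
#' @param path FASTA file with at least one record.
#' @param cds_start CDS coordinate of the record's first base.
#' @param name Optional transcript name (defaults to the FASTA header).
#' @return A `mini_transcript` with a single exon segment.
#' @export
read_transcript_fasta <- function(path, cds_start, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    be_stop(sprintf("no sequences in %s", dQuote(path)),
            "bescreen_validation_error")
  }
  mini_transcript(
    list(list(kind = "exon", sequence = as.character(seqs[[1]]))),
    cds_start = cds_start,
    name = if (is.null(name)) names(seqs)[1] else name
  )
}
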