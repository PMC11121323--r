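#' Enumerate protospacer placements for one construct
#'
#' For every editing-window position `p`, the protospacer is placed so the
#' variant's mutant base sits at protospacer position `p` on the targeted
#' strand (genomically contiguous: placements may run from exon into intron),
#' and a candidate is emitted iff the adjacent PAM matches the construct's
#' IUPAC pattern. Enumeration works on the mutant sequence: if `transcript`
#' carries the reference allele at the variant position the mutant allele is
#' installed first.
#'
#' Placements whose protospacer or PAM would leave the modeled sequence, or
#' overlap a flank segment (unmodeled filler whose identity cannot be
#' trusted), are skipped with a consolidated warning.
#'
#' Candidates are sorted by distance of the target from the window midpoint,
#' then by window position, so results are deterministic.
#'
#' @param transcript A [mini_transcript()].
#' @param variant A [be_variant()] with an exonic or intronic coding position
#'   inside the modeled slice.
#' @param construct An [editor_construct()].
#' @param strategy An `edit_strategy` from [classify_variant()]; its editor
#'   class must match the construct's conversion.
#' @return List of `guide_candidate` objects (possibly empty). Each carries
#'   `construct_name`, `strand`, `protospacer` (targeted strand, 5'->3',
#'   mutant allele included), `pam`, `target_window_position`, `span`
#'   (per-protospacer-position coordinate map), `contains_intronic`, and the
#'   genomic `proto_range`/`pam_range`.
#' @export
enumerate_guides <- function(transcript, variant, construct, strategy) {
  stopifnot(inherits(transcript, "mini_transcript"),
            inherits(variant, "be_variant"),
            inherits(construct, "editor_construct"),
            inherits(strategy, "edit_strategy"))
  if (!is_correctable_by(strategy, construct)) {
    be_stop(sprintf("construct %s (%s>%s) cannot implement a %s strategy",
                    dQuote(construct$name), construct$conversion["from"],
                    construct$conversion["to"], strategy$editor_class),
            "bescreen_domain_error")
  }

  mt <- install_mutant(transcript, variant)
  v_gi <- resolve_position(mt, variant$position)
  N <- nchar(mt$seq)
  L <- construct$spacer_length
  P <- nchar(construct$pam)
  ws <- construct$window[["start"]]
  we <- construct$window[["end"]]
  strand <- strategy$target_strand

  candidates <- list()
  n_skipped <- 0L
  for (p in ws:we) {
    if (strand == "forward") {
      proto <- c(v_gi - (p - 1L), v_gi + (L - p))
      pam <- if (construct$pam_side == "3prime") {
        c(proto[2] + 1L, proto[2] + P)
      } else {
        c(proto[1] - P, proto[1] - 1L)
      }
    } else {
      proto <- c(v_gi - (L - p), v_gi + (p - 1L))
      # the 3' end of a reverse-strand protospacer is the genomic left end
      pam <- if (construct$pam_side == "3prime") {
        c(proto[1] - P, proto[1] - 1L)
      } else {
        c(proto[2] + 1L, proto[2] + P)
      }
    }
    lo <- min(proto[1], pam[1]); hi <- max(proto[2], pam[2])
    if (lo < 1L || hi > N || any(mt$map$kind[lo:hi] == "flank")) {
      n_skipped <- n_skipped + 1L
      next
    }
    proto_fwd <- substr(mt$seq, proto[1], proto[2])
    pam_fwd <- substr(mt$seq, pam[1], pam[2])
    proto_seq <- if (strand == "forward") proto_fwd else revcomp(proto_fwd)
    pam_seq <- if (strand == "forward") pam_fwd else revcomp(pam_fwd)
    stopifnot(substr(proto_seq, p, p) == strategy$mutant_base_on_target_strand)
    if (!iupac_match(construct$pam, pam_seq)) next

    genomic <- if (strand == "forward") proto[1]:proto[2] else proto[2]:proto[1]
    span <- mt$map[genomic, c("genomic", "base", "kind", "anchor", "offset", "cds")]
    span$proto_pos <- seq_len(L)
    span$label <- render_map_label(span)
    rownames(span) <- NULL
    candidates[[length(candidates) + 1L]] <- structure(
      list(construct_name = construct$name,
           strand = strand,
           protospacer = proto_seq,
           pam = pam_seq,
           target_window_position = p,
           span = span,
           contains_intronic = any(span$kind != "exon"),
           proto_range = proto,
           pam_range = pam),
      class = "guide_candidate"
    )
  }
  if (n_skipped > 0L) {
    warning(sprintf(
      "%s / %s: %d placement(s) skipped (protospacer or PAM outside the modeled exon/intron sequence)",
      construct$name, format_variant(variant), n_skipped), call. = FALSE)
  }
  mid <- (ws + we) / 2
  ord <- order(abs(vapply(candidates, `[[`, 0L, "target_window_position") - mid),
               vapply(candidates, `[[`, 0L, "target_window_position"))
  candidates[ord]
}

#' @export
print.guide_candidate <- function(x, ...) {
  cat(sprintf("%s [%s strand] %s | PAM %s (target at protospacer position %d)\n",
              x$construct_name, x$strand, x$protospacer, tolower(x$pam),
              x$target_window_position))
  invisible(x)
}

# Install the mutant allele; the transcript may already carry it.
install_mutant <- function(transcript, variant) {
  cur <- get_base(transcript, variant$position)
  if (cur == variant$alt) return(transcript)
  if (cur != variant$ref) {
    be_stop(sprintf(
      "transcript carries %s at c.%s; variant %s expects ref %s or alt %s",
      cur, format_c_position(variant$position), format_variant(variant),
      variant$ref, variant$alt), "bescreen_validation_error")
  }
  apply_edit(transcript, variant$position, variant$alt)
}

#' Per-construct guide availability matrix for one variant
#'
#' Runs [classify_variant()] and, for each construct whose conversion matches
#' the strategy, [enumerate_guides()]; reports the candidate count per
#' construct and the best (first in sorted order) candidate.
#'
#' @inheritParams enumerate_guides
#' @param registry Named list of constructs, defaults to [default_registry()].
#' @return A `screen_matrix`: list with `variant`, `strategy` (or `NULL` if
#'   not amenable), named integer `counts`, and named lists `best` / `guides`.
#' @export
screen_matrix <- function(transcript, variant, registry = default_registry()) {
  stopifnot(inherits(transcript, "mini_transcript"),
            inherits(variant, "be_variant"))
  strategies <- classify_variant(variant$ref, variant$alt)
  strategy <- if (length(strategies) > 0) strategies[[1]] else NULL
  counts <- stats::setNames(integer(length(registry)), names(registry))
  best <- guides <- stats::setNames(vector("list", length(registry)),
                                    names(registry))
  if (!is.null(strategy)) {
    for (nm in names(registry)) {
      if (!is_correctable_by(strategy, registry[[nm]])) next
      g <- enumerate_guides(transcript, variant, registry[[nm]], strategy)
      counts[[nm]] <- length(g)
      guides[[nm]] <- g
      if (length(g) > 0) best[[nm]] <- g[[1]]
    }
  }
  structure(
    list(variant = variant, strategy = strategy, counts = counts,
         best = best, guides = guides),
    class = "screen_matrix"
  )
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(format_variant(x$variant), "-> ")
  if (is.null(x$strategy)) {
    cat("not amenable to base editing\n")
  } else {
    cat(sprintf("%s targeting the %s strand\n",
                x$strategy$editor_class, x$strategy$target_strand))
  }
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %d guide(s)%s\n", nm, x$counts[[nm]],
                if (!is.null(x$best[[nm]]))
                  paste0(": ", x$best[[nm]]$protospacer, " | ",
                         tolower(x$best[[nm]]$pam)) else ""))
  }
  invisible(x)
}
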