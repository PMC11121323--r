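#' Editable positions inside a guide's window
#'
#' Every protospacer position inside the editing window whose targeted-strand
#' base equals the construct's substrate base (A for an ABE) is editable; the
#' intended target is separated from the bystanders.
#'
#' @param guide A `guide_candidate` produced for `construct`.
#' @param construct The [editor_construct()] the guide was designed for.
#' @return List with integer `target` and integer vector `bystanders` (window
#'   positions, ascending).
#' @export
editable_positions <- function(guide, construct) {
  stopifnot(inherits(guide, "guide_candidate"),
            inherits(construct, "editor_construct"))
  substrate <- construct$conversion[["from"]]
  chars <- strsplit(guide$protospacer, "", fixed = TRUE)[[1]]
  win <- construct$window[["start"]]:construct$window[["end"]]
  editable <- win[chars[win] == substrate]
  target <- guide$target_window_position
  if (!target %in% editable) {
    be_stop("target base is not editable by this construct (internal inconsistency)",
            "bescreen_domain_error")
  }
  list(target = target, bystanders = setdiff(editable, target))
}

# Coding-strand ref/alt of a conversion performed on the given strand.
project_conversion <- function(conversion, strand) {
  if (strand == "forward") {
    c(ref = conversion[["from"]], alt = conversion[["to"]])
  } else {
    c(ref = comp_base(conversion[["from"]]), alt = comp_base(conversion[["to"]]))
  }
}

#' Annotate the consequence of one window edit
#'
#' Computes the coding-strand base change (an A-to-G edit on the reverse
#' strand projects as T>C on the coding strand), renders the c. label, and
#' classifies the consequence: intronic offsets +/-1 or +/-2 are canonical
#' splice sites, +/-3..8 the splice region, larger offsets (and flank filler)
#' plain intronic; exonic edits are classified by comparing the pre-edit codon
#' with the edited codon (silent / missense / nonsense / start_loss). Codons
#' truncated by the edge of the modeled slice yield `incomplete_codon` with a
#' warning.
#'
#' @param transcript The baseline transcript (normally the mutant allele).
#' @param coding_pos Position of the edited base.
#' @param strand `"forward"` or `"reverse"`: the strand the editor acts on.
#' @param conversion `c(from, to)` conversion on the targeted strand.
#' @return A `bystander_edit`: list with `coding_pos`, `c_label`,
#'   `consequence_class`, `p_label` (empty string for non-coding classes),
#'   `codon_index` (NA for non-exonic edits).
#' @export
annotate_edit <- function(transcript, coding_pos, strand = "forward",
                          conversion = c(from = "A", to = "G")) {
  stopifnot(inherits(transcript, "mini_transcript"))
  pos <- as_coding_position(coding_pos)
  strand <- match.arg(strand, c("forward", "reverse"))
  proj <- project_conversion(conversion, strand)
  cur <- get_base(transcript, pos)
  if (cur != proj[["ref"]]) {
    be_stop(sprintf(
      "base at c.%s is %s, not a substrate of the %s>%s conversion on the %s strand",
      format_c_position(pos), cur, conversion[["from"]], conversion[["to"]], strand),
      "bescreen_domain_error")
  }
  c_label <- sprintf("c.%s%s>%s", format_c_position(pos), proj[["ref"]], proj[["alt"]])

  gi <- resolve_position(transcript, pos)
  kind <- transcript$map$kind[gi]
  if (kind != "exon") {
    off <- abs(pos$offset)
    class <- if (kind == "flank") "intronic"
    else if (off <= 2L) "canonical_splice"
    else if (off <= 8L) "splice_region"
    else "intronic"
    return(new_bystander_edit(pos, c_label, class, "", NA_integer_))
  }

  idx <- c_to_codon(pos$base)$index
  before <- codon_sequence(transcript, idx)
  if (!before$complete) {
    warning(sprintf("codon %d is incomplete in the modeled slice; consequence not called",
                    idx), call. = FALSE)
    return(new_bystander_edit(pos, c_label, "incomplete_codon", "", idx))
  }
  after <- codon_sequence(apply_edit(transcript, pos, proj[["alt"]]), idx)
  class <- if (after$aa == before$aa) "silent"
  else if (after$aa == "*") "nonsense"
  else if (before$aa == "M" && idx == 1L && transcript$cds_start == 1L) "start_loss"
  else "missense"
  p_label <- sprintf("p.%s%d%s", before$aa3, idx, after$aa3)
  new_bystander_edit(pos, c_label, class, p_label, idx)
}

new_bystander_edit <- function(pos, c_label, class, p_label, codon_index) {
  structure(
    list(coding_pos = pos, c_label = c_label, consequence_class = class,
         p_label = p_label, codon_index = codon_index),
    class = "bystander_edit"
  )
}

#' @export
print.bystander_edit <- function(x, ...) {
  cat(sprintf("%s  %s%s\n", x$c_label, x$consequence_class,
              if (nzchar(x$p_label)) paste0("  ", x$p_label) else ""))
  invisible(x)
}

# span row (as a one-row data.frame) -> coding_position
span_coding_position <- function(span, proto_pos) {
  row <- span[span$proto_pos == proto_pos, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  coding_position(row$anchor, row$offset)
}

#' Combinatorial amino-acid outcomes per affected codon
#'
#' Window-editable positions (target included) are grouped by the codon they
#' fall in; within each codon every on/off combination of the edits is
#' translated, mirroring the slash notation used for reporting bystander
#' outcomes (e.g. Q944Q/R: the codon can end up Gln or Arg depending on which
#' adenines the deaminase converts). Each editable base is treated as
#' independently edited or not.
#'
#' The reference amino acid of each set is the wild-type one: if the codon
#' contains the target, the target base is first restored to the corrected
#' allele. Codons reachable only as wild type are omitted, as are codons whose
#' only editable base is the target itself (correcting the target is the
#' intention, not a bystander outcome).
#'
#' @inheritParams editable_positions
#' @param transcript Baseline transcript carrying the mutant allele.
#' @param variant The targeted [be_variant()].
#' @return List of `codon_outcome_set`: `codon_index`, `wt_aa` (one-letter),
#'   `outcomes` (sorted unique one-letter codes reachable across edit
#'   combinations), `label` (e.g. `"Q944Q/R"`).
#' @export
codon_outcomes <- function(transcript, guide, construct, variant) {
  stopifnot(inherits(transcript, "mini_transcript"),
            inherits(guide, "guide_candidate"),
            inherits(construct, "editor_construct"),
            inherits(variant, "be_variant"))
  mt <- install_mutant(transcript, variant)
  ed <- editable_positions(guide, construct)
  proj <- project_conversion(construct$conversion, guide$strand)

  # exonic editable positions with their cds coordinate
  all_pos <- sort(c(ed$target, ed$bystanders))
  info <- lapply(all_pos, function(p) {
    row <- guide$span[guide$span$proto_pos == p, , drop = FALSE]
    if (row$kind != "exon") return(NULL)
    list(proto_pos = p, cds = row$cds, is_target = p == ed$target)
  })
  info <- Filter(Negate(is.null), info)
  if (length(info) == 0L) return(list())

  codons <- vapply(info, function(x) c_to_codon(x$cds)$index, 0L)
  out <- list()
  for (idx in sort(unique(codons))) {
    members <- info[codons == idx]
    if (all(vapply(members, `[[`, TRUE, "is_target"))) next
    ref <- codon_sequence(mt, idx)
    if (!ref$complete) {
      warning(sprintf("codon %d incomplete; outcome set not enumerated", idx),
              call. = FALSE)
      next
    }
    span <- codon_span(idx)
    within <- vapply(members, function(x) match(x$cds, span), 0L)
    mutant_codon <- strsplit(ref$bases, "", fixed = TRUE)[[1]]

    # wild-type reference: restore the target allele if it sits in this codon
    wt_codon <- mutant_codon
    tgt <- which(vapply(members, `[[`, TRUE, "is_target"))
    if (length(tgt) == 1L) wt_codon[within[tgt]] <- variant$ref
    wt_aa <- translate_codon(paste(wt_codon, collapse = ""))

    k <- length(members)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    outcomes <- apply(combos, 1L, function(onoff) {
      codon <- mutant_codon
      codon[within[onoff]] <- proj[["alt"]]
      translate_codon(paste(codon, collapse = ""))
    })
    outcomes <- sort(unique(outcomes))
    if (identical(outcomes, wt_aa)) next
    out[[length(out) + 1L]] <- structure(
      list(codon_index = idx, wt_aa = wt_aa, outcomes = outcomes,
           label = sprintf("%s%d%s", wt_aa, idx, paste(outcomes, collapse = "/"))),
      class = "codon_outcome_set"
    )
  }
  out
}

#' @export
print.codon_outcome_set <- function(x, ...) {
  cat(sprintf("codon %d: %s -> {%s}  (%s)\n", x$codon_index, x$wt_aa,
              paste(x$outcomes, collapse = ", "), x$label))
  invisible(x)
}

#' Full bystander report for one guide
#'
#' One annotated entry per bystander window position (ascending), the
#' per-codon outcome summary, and a check that editing the target base alone
#' restores the wild-type amino acid.
#'
#' @inheritParams codon_outcomes
#' @return A `bystander_report`: list with `edits` (data.frame: window
#'   position, c. label, consequence class, p. label), `edit_objects`,
#'   `outcomes` (from [codon_outcomes()]), and `target_restores_wt`.
#' @export
bystander_report <- function(transcript, guide, construct, variant) {
  mt <- install_mutant(transcript, variant)
  ed <- editable_positions(guide, construct)
  objs <- lapply(ed$bystanders, function(p) {
    annotate_edit(mt, span_coding_position(guide$span, p),
                  strand = guide$strand, conversion = construct$conversion)
  })
  edits <- data.frame(
    window_position = ed$bystanders,
    c_label = vapply(objs, `[[`, "", "c_label"),
    consequence_class = vapply(objs, `[[`, "", "consequence_class"),
    p_label = vapply(objs, `[[`, "", "p_label"),
    stringsAsFactors = FALSE
  )

  # editing the target alone must restore the wild-type amino acid
  tgt_pos <- span_coding_position(guide$span, ed$target)
  proj <- project_conversion(construct$conversion, guide$strand)
  restored <- apply_edit(mt, tgt_pos, proj[["alt"]])
  restores <- get_base(restored, tgt_pos) == variant$ref
  if (restores && tgt_pos$offset == 0L) {
    idx <- c_to_codon(tgt_pos$base)$index
    cod <- codon_sequence(restored, idx)
    wt <- codon_sequence(apply_edit(mt, tgt_pos, variant$ref), idx)
    if (cod$complete && wt$complete) restores <- cod$aa == wt$aa
  }
  structure(
    list(guide = guide, variant = variant, edits = edits, edit_objects = objs,
         outcomes = codon_outcomes(mt, guide, construct, variant),
         target_restores_wt = restores),
    class = "bystander_report"
  )
}

#' @export
print.bystander_report <- function(x, ...) {
  cat(sprintf("%s (%s): %d bystander edit(s)\n",
              format_variant(x$variant), x$guide$construct_name, nrow(x$edits)))
  for (i in seq_len(nrow(x$edits))) {
    e <- x$edits[i, ]
    cat(sprintf("  pos %2d  %-14s %-16s %s\n", e$window_position, e$c_label,
                e$consequence_class, e$p_label))
  }
  if (length(x$outcomes) > 0) {
    cat("  codon outcomes:",
        paste(vapply(x$outcomes, `[[`, "", "label"), collapse = ", "), "\n")
  }
  cat("  target edit restores wild type:", x$target_restores_wt, "\n")
  invisible(x)
}
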