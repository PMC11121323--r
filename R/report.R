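#' Render a guide in the publication display convention
#'
#' Protospacer uppercase on the targeted strand with the target base replaced
#' by `[WT>MUT]` (alleles on the targeted strand), PAM appended in lowercase
#' on its side. The editing window cannot be underlined in plain text; its
#' protospacer indices travel as the `window` attribute of the returned
#' string.
#'
#' @param guide A `guide_candidate`.
#' @param variant The targeted [be_variant()].
#' @param strategy The `edit_strategy` the guide implements.
#' @param construct The [editor_construct()] (for the window annotation).
#' @return Display string, e.g. `"TTAG[G>A]TATTGCAAATGCTGTTtttaat"`, with an
#'   integer `window` attribute `c(start, end)`.
#' @export
format_guide_display <- function(guide, variant, strategy, construct = NULL) {
  stopifnot(inherits(guide, "guide_candidate"),
            inherits(variant, "be_variant"),
            inherits(strategy, "edit_strategy"))
  p <- guide$target_window_position
  proto <- toupper(guide$protospacer)
  wt <- strategy$corrected_base_on_target_strand
  mut <- strategy$mutant_base_on_target_strand
  body <- paste0(substr(proto, 1L, p - 1L), "[", wt, ">", mut, "]",
                 substr(proto, p + 1L, nchar(proto)))
  pam <- tolower(guide$pam)
  out <- if (pam_side_of(guide) == "3prime") paste0(body, pam) else paste0(pam, body)
  if (!is.null(construct)) {
    attr(out, "window") <- unname(as.integer(construct$window))
  }
  out
}

# PAM side recovered from the candidate geometry.
pam_side_of <- function(guide) {
  if (guide$strand == "forward") {
    if (guide$pam_range[1] > guide$proto_range[2]) "3prime" else "5prime"
  } else {
    if (guide$pam_range[2] < guide$proto_range[1]) "3prime" else "5prime"
  }
}

#' Coding-strand rendering of the targeted change
#'
#' The companion view of the bracket notation: alleles on the coding strand
#' (a reverse-strand guide whose targeted-strand change is G>A reads C>T
#' here).
#'
#' @inheritParams format_guide_display
#' @return E.g. `"c.2234C>T"`.
#' @export
format_coding_change <- function(variant) {
  format_variant(variant)
}

#' Screen variants against an editor registry
#'
#' The full pipeline: amenability classification, per-construct guide
#' enumeration, and bystander analysis for every candidate guide. The result
#' table has one row per variant x construct; regenerating it from the same
#' inputs is byte-identical (stable ordering, no timestamps in the body).
#'
#' @param transcript A [mini_transcript()].
#' @param variants A [be_variant()] or list of them.
#' @param registry Named list of constructs, defaults to [default_registry()].
#' @return A `screen_report`: list with `table` (data.frame), `details`
#'   (per-variant [screen_matrix()] + bystander reports), and `metadata`.
#' @export
screen_variants <- function(transcript, variants, registry = default_registry()) {
  stopifnot(inherits(transcript, "mini_transcript"))
  if (inherits(variants, "be_variant")) variants <- list(variants)
  if (length(variants) == 0L) {
    be_stop("no variants to screen", "bescreen_validation_error")
  }
  rows <- list()
  details <- list()
  for (v in variants) {
    sm <- screen_matrix(transcript, v, registry)
    vb <- list()
    for (nm in names(registry)) {
      g <- sm$best[[nm]]
      if (is.null(g)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = format_variant(v), construct = nm,
          n_guides = unname(sm$counts[[nm]]),
          strand = if (is.null(sm$strategy)) "" else sm$strategy$target_strand,
          protospacer = "", pam = "", target_pos = NA_integer_,
          display_string = "", n_bystanders = NA_integer_,
          bystander_labels = "", codon_outcome_labels = "",
          coding_change = format_variant(v),
          stringsAsFactors = FALSE
        )
        next
      }
      br <- bystander_report(transcript, g, registry[[nm]], v)
      vb[[nm]] <- br
      labels <- ifelse(nzchar(br$edits$p_label), br$edits$p_label,
                       br$edits$c_label)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = format_variant(v), construct = nm,
        n_guides = unname(sm$counts[[nm]]),
        strand = g$strand,
        protospacer = g$protospacer, pam = g$pam,
        target_pos = g$target_window_position,
        display_string = as.character(
          format_guide_display(g, v, sm$strategy, registry[[nm]])),
        n_bystanders = length(br$edits$window_position),
        bystander_labels = paste(labels, collapse = ";"),
        codon_outcome_labels = paste(
          vapply(br$outcomes, `[[`, "", "label"), collapse = ";"),
        coding_change = format_variant(v),
        stringsAsFactors = FALSE
      )
    }
    details[[format_variant(v)]] <- list(matrix = sm, bystanders = vb)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(table = table,
         details = details,
         metadata = list(
           package = "bescreen",
           version = as.character(utils::packageVersion("bescreen")),
           transcript = transcript$name,
           registry_hash = registry_fingerprint(registry),
           n_variants = length(variants))),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen_report: %d variant(s) x %d construct(s) on %s\n",
              x$metadata$n_variants,
              nrow(x$table) / max(1L, x$metadata$n_variants),
              dQuote(x$metadata$transcript)))
  shown <- x$table[x$table$n_guides > 0,
                   c("variant", "construct", "n_guides", "strand",
                     "display_string", "n_bystanders")]
  if (nrow(shown) > 0) print(shown, row.names = FALSE) else
    cat("  no guides found for any construct\n")
  invisible(x)
}

#' Write a screen report to TSV or JSON
#'
#' TSV carries the fixed-column result table (tab-separated, header row, LF);
#' JSON mirrors the full report (metadata + table, sorted keys) and can be
#' read back with [read_report()].
#'
#' @param report A `screen_report`.
#' @param path Output file, or `NULL` to return the document as a string.
#' @param format `"tsv"` or `"json"`.
#' @return `path` (or the document text when `path` is `NULL`), invisibly.
#' @export
write_report <- function(report, path = NULL, format = c("tsv", "json")) {
  stopifnot(inherits(report, "screen_report"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- if (is.null(path)) textConnection("out", "w", local = TRUE) else
      file(path, "w")
    utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    close(con)
    if (is.null(path)) return(invisible(paste(out, collapse = "\n")))
  } else {
    doc <- jsonlite::toJSON(
      list(metadata = report$metadata, table = report$table),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (is.null(path)) return(invisible(as.character(doc)))
    writeLines(doc, path)
  }
  invisible(path)
}

#' Read a JSON screen report back
#' @param path JSON file written by [write_report()].
#' @return A `screen_report` (table + metadata; per-guide detail objects are
#'   not serialized).
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  table <- doc$table
  # restore empty-string columns dropped to NA and integer types
  for (col in c("variant", "construct", "strand", "protospacer", "pam",
                "display_string", "bystander_labels", "codon_outcome_labels",
                "coding_change")) {
    if (is.null(table[[col]])) table[[col]] <- ""
    table[[col]][is.na(table[[col]])] <- ""
  }
  for (col in c("n_guides", "target_pos", "n_bystanders")) {
    table[[col]] <- as.integer(table[[col]])
  }
  structure(list(table = table, details = NULL, metadata = doc$metadata),
            class = "screen_report")
}
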