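#' Base-editor construct definition
#'
#' An `editor_construct` bundles a construct's targeting rules: the PAM
#' pattern (IUPAC) and its side relative to the protospacer on the targeted
#' strand, the spacer length, the editing window (inclusive protospacer
#' positions, 1-based from the protospacer 5' end), and the base conversion
#' the deaminase performs.
#'
#' @param name Construct name.
#' @param pam IUPAC PAM pattern, e.g. `"NNGRRT"`.
#' @param pam_side `"3prime"` or `"5prime"` relative to the protospacer on the
#'   targeted strand.
#' @param spacer_length Protospacer length in nt.
#' @param window Integer vector `c(start, end)`, inclusive protospacer
#'   positions of the editing window.
#' @param conversion Two-element character vector `c(from, to)`; `c("A","G")`
#'   for an adenine base editor.
#' @param note Free-text confidence/provenance note.
#' @return An object of class `editor_construct`.
#' @export
editor_construct <- function(name, pam, pam_side = c("3prime", "5prime"),
                             spacer_length, window, conversion,
                             note = "") {
  assert_string1(name, "name")
  assert_string1(pam, "pam")
  pam_side <- match.arg(pam_side)
  pam <- toupper(pam)
  if (nchar(pam) == 0L || grepl("[^ACGTRYSWKMBDHVN]", pam)) {
    be_stop(sprintf("PAM pattern %s is not a non-empty IUPAC string", dQuote(pam)),
            "bescreen_parse_error")
  }
  spacer_length <- as.integer(spacer_length)
  window <- as.integer(window)
  if (length(window) != 2L || anyNA(window) || window[1] < 1L ||
      window[1] > window[2] || window[2] > spacer_length) {
    be_stop(sprintf(
      "editing window must satisfy 1 <= start <= end <= spacer_length (%d)",
      spacer_length), "bescreen_validation_error")
  }
  conversion <- toupper(as.character(conversion))
  if (length(conversion) != 2L || !all(conversion %in% DNA_BASES) ||
      conversion[1] == conversion[2]) {
    be_stop("conversion must be two distinct bases c(from, to)",
            "bescreen_validation_error")
  }
  structure(
    list(name = name, pam = pam, pam_side = pam_side,
         spacer_length = spacer_length,
         window = c(start = window[1], end = window[2]),
         conversion = c(from = conversion[1], to = conversion[2]),
         note = as.character(note)),
    class = "editor_construct"
  )
}

#' @export
print.editor_construct <- function(x, ...) {
  cat(sprintf("%s: %d-nt spacer, PAM %s (%s), window %d-%d, %s>%s\n",
              x$name, x$spacer_length, x$pam, x$pam_side,
              x$window["start"], x$window["end"],
              x$conversion["from"], x$conversion["to"]))
  if (nzchar(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Default ABE8e construct registry
#'
#' The four adenine base-editor constructs screened by the pipeline, all
#' performing the A-to-G conversion on the targeted strand:
#'
#' * `nSpCas9-ABE8e` - PAM NGG (3'), 20-nt spacer, window 4-8.
#' * `nSaCas9-ABE8e` - PAM NNGRRT (3'), 21-nt spacer, window 3-13.
#' * `KKH-nSaCas9-ABE8e` - PAM NNNRRT (3', relaxed SaCas9 PAM), 21-nt spacer,
#'   window 3-13.
#' * `CasMINI-ABE8e` - PAM TTTR (5'), 20-nt spacer, window 3-8.
#'
#' Editing windows are configuration, not constants: override any field via
#' [load_registry()]. The CasMINI defaults come from the Cas12f construct
#' literature and carry a low-confidence note.
#'
#' @return Named list of `editor_construct` objects.
#' @export
default_registry <- function() {
  reg <- list(
    editor_construct("nSpCas9-ABE8e", "NGG", "3prime", 20L, c(4L, 8L),
                     c("A", "G")),
    editor_construct("nSaCas9-ABE8e", "NNGRRT", "3prime", 21L, c(3L, 13L),
                     c("A", "G")),
    editor_construct("KKH-nSaCas9-ABE8e", "NNNRRT", "3prime", 21L, c(3L, 13L),
                     c("A", "G")),
    editor_construct("CasMINI-ABE8e", "TTTR", "5prime", 20L, c(3L, 8L),
                     c("A", "G"),
                     note = paste("no worked example in source; defaults from",
                                  "construct literature, configurable"))
  )
  names(reg) <- vapply(reg, `[[`, "", "name")
  reg
}

#' Look up a construct by name
#' @param name Construct name.
#' @param registry Registry (named list), defaults to [default_registry()].
#' @return An `editor_construct`.
#' @export
get_construct <- function(name, registry = default_registry()) {
  assert_string1(name, "name")
  if (!name %in% names(registry)) {
    be_stop(sprintf("unknown construct %s; known constructs: %s", dQuote(name),
                    paste(names(registry), collapse = ", ")),
            "bescreen_lookup_error")
  }
  registry[[name]]
}

#' Load an editor registry from a config document
#'
#' Reads a YAML or JSON file holding a list of construct entries (fields as in
#' [editor_construct()]: `name`, `pam`, `pam_side`, `spacer_length`, `window`,
#' `conversion`, optional `note`). Entries override or extend `base` by name.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @param base Registry to override; `NULL` starts from an empty registry.
#' @return Named list of `editor_construct` objects.
#' @export
load_registry <- function(path, base = default_registry()) {
  format <- infer_format(path)
  doc <- if (format == "yaml") yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(doc)) {
    be_stop(sprintf("registry config %s is not a list of constructs",
                    dQuote(path)), "bescreen_validation_error")
  }
  reg <- if (is.null(base)) list() else base
  for (entry in doc) {
    ec <- editor_construct(
      name = entry$name, pam = entry$pam,
      pam_side = if (is.null(entry$pam_side)) "3prime" else entry$pam_side,
      spacer_length = entry$spacer_length,
      window = unlist(entry$window),
      conversion = unlist(entry$conversion),
      note = if (is.null(entry$note)) "" else entry$note
    )
    reg[[ec$name]] <- ec
  }
  reg
}

#' Write a registry to a config document
#' @param registry Named list of `editor_construct` objects.
#' @param path Output file (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  format <- infer_format(path)
  doc <- lapply(unname(registry), function(ec) {
    list(name = ec$name, pam = ec$pam, pam_side = ec$pam_side,
         spacer_length = ec$spacer_length,
         window = unname(as.integer(ec$window)),
         conversion = unname(ec$conversion), note = ec$note)
  })
  if (format == "yaml") yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Stable fingerprint of a registry (for report metadata).
registry_fingerprint <- function(registry) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_registry(registry, tmp)
  unname(tools::md5sum(tmp))
}
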