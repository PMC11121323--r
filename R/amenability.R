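#' Variants and edit strategies
#'
#' A variant is a coding-strand SNV: a coding position plus reference and
#' alternate alleles (e.g. c.2843G>A). An edit strategy states which editor
#' class can revert it and on which strand the substrate base sits.
#'
#' @param position Coding position (object, integer, or string such as
#'   `"2843"`).
#' @param ref,alt Reference / alternate base on the coding strand.
#' @return A `be_variant`.
#' @examples
#' be_variant(2843, "G", "A")
#' parse_variant("c.2234C>T")
#' @export
be_variant <- function(position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) {
    be_stop("ref and alt must be single bases over ACGT", "bescreen_domain_error")
  }
  if (ref == alt) {
    be_stop("ref and alt must differ", "bescreen_domain_error")
  }
  structure(list(position = as_coding_position(position), ref = ref, alt = alt),
            class = "be_variant")
}

#' @rdname be_variant
#' @param text Variant string, e.g. `"c.2843G>A"` or `"2843-2A>G"`.
#' @export
parse_variant <- function(text) {
  assert_string1(text, "text")
  s <- sub("^c\\.", "", trimws(text))
  m <- regmatches(s, regexec("^(\\d+(?:[+-]\\d+)?)([ACGTacgt])>([ACGTacgt])$", s))[[1]]
  if (length(m) == 0L) {
    be_stop(sprintf("malformed variant %s", dQuote(text)), "bescreen_parse_error")
  }
  be_variant(parse_c_position(m[2]), m[3], m[4])
}

#' Render a variant as a c. label
#' @param v A `be_variant`.
#' @return E.g. `"c.2843G>A"`.
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "be_variant"))
  sprintf("c.%s%s>%s", format_c_position(v$position), v$ref, v$alt)
}

#' @export
print.be_variant <- function(x, ...) {
  cat(format_variant(x), "\n")
  invisible(x)
}

# Editor classes and their on-target-strand conversions.
CLASS_CONVERSION <- list(
  ABE = c(from = "A", to = "G"),
  CBE = c(from = "C", to = "T"),
  CGBE = c(from = "C", to = "G")
)

# ref>alt (coding strand) -> amenable strategy. Exactly the six substitutions
# current editors can revert: the four transitions plus the two C:G<->G:C
# transversions.
AMENABLE_TABLE <- list(
  "G>A" = list(editor_class = "ABE", target_strand = "forward"),
  "C>T" = list(editor_class = "ABE", target_strand = "reverse"),
  "A>G" = list(editor_class = "CBE", target_strand = "reverse"),
  "T>C" = list(editor_class = "CBE", target_strand = "forward"),
  "G>C" = list(editor_class = "CGBE", target_strand = "forward"),
  "C>G" = list(editor_class = "CGBE", target_strand = "reverse")
)

#' Decide whether an SNV is base-editable, by which class, on which strand
#'
#' The substrate of the edit is the MUTANT allele: an ABE targeting the
#' forward strand converts the pathogenic A back to G; a C>T variant reads
#' as A on the reverse strand and is reverted there. The returned strategy
#' carries the mutant and corrected base on the targeted strand; converting
#' the mutant base and projecting back to the coding strand restores `ref`.
#'
#' @param ref,alt Reference / alternate base on the coding strand.
#' @return List of `edit_strategy` objects (length 1 for the six amenable
#'   substitutions, empty otherwise).
#' @examples
#' classify_variant("G", "A") # ABE, forward strand
#' classify_variant("A", "T") # not amenable -> empty list
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is.character(ref) || !is.character(alt) ||
      !ref %in% DNA_BASES || !alt %in% DNA_BASES) {
    be_stop("ref and alt must be single bases over ACGT", "bescreen_domain_error")
  }
  if (ref == alt) be_stop("ref and alt must differ", "bescreen_domain_error")
  hit <- AMENABLE_TABLE[[paste0(ref, ">", alt)]]
  if (is.null(hit)) return(list())
  conv <- CLASS_CONVERSION[[hit$editor_class]]
  mut_on_target <- if (hit$target_strand == "forward") alt else comp_base(alt)
  cor_on_target <- if (hit$target_strand == "forward") ref else comp_base(ref)
  stopifnot(mut_on_target == conv[["from"]], cor_on_target == conv[["to"]])
  list(structure(
    list(editor_class = hit$editor_class,
         target_strand = hit$target_strand,
         mutant_base_on_target_strand = mut_on_target,
         corrected_base_on_target_strand = cor_on_target,
         ref = ref, alt = alt),
    class = "edit_strategy"
  ))
}

#' @export
print.edit_strategy <- function(x, ...) {
  cat(sprintf("%s targeting the %s strand (%s>%s on targeted strand)\n",
              x$editor_class, x$target_strand,
              x$mutant_base_on_target_strand, x$corrected_base_on_target_strand))
  invisible(x)
}

#' Can a construct implement a strategy?
#' @param strategy An `edit_strategy`.
#' @param construct An `editor_construct`.
#' @return `TRUE` iff the construct's conversion matches the strategy's editor
#'   class.
#' @export
is_correctable_by <- function(strategy, construct) {
  stopifnot(inherits(strategy, "edit_strategy"),
            inherits(construct, "editor_construct"))
  conv <- CLASS_CONVERSION[[strategy$editor_class]]
  identical(unname(conv), unname(construct$conversion))
}
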