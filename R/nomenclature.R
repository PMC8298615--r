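# HGVS nomenclature: parsing, classification and formatting of the cDNA and
# protein variant descriptions that occur in curated registries of small
# pathogenic variants (substitutions, duplications, deletions, insertions,
# delins; missense, nonsense, frameshift, in-frame deletion, start loss,
# stop loss).  Coordinates are 1-based cDNA positions on the transcript, with
# signed intronic offsets (c.400+2, c.81-3).  This is deliberately not a full
# HGVS implementation: only the constructs needed for single-gene variant
# registries are supported, and no transcript-to-genome projection is done.

# Coding span of the APRT transcript NM_000485.2: 180 codons + stop = 543 nt.
.CDS_LENGTH <- 543L
# 180 residues + the stop codon position 181.
.MAX_CODON <- 181L

.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

#' Parse an HGVS cDNA description
#'
#' Parses descriptions of the forms `c.194A>T`, `c.81-3C>G`, `c.400+2dup`,
#' `c.23dup`, `c.521_523del`, `c.x_yins...`, `c.x_ydelins...`.  Internal
#' whitespace (as in `c.400 + 2dup`) is stripped before parsing, so the
#' canonical formatted output never contains spaces.
#'
#' @param text a single HGVS cDNA string beginning with `"c."`.
#' @return an object of class `"cdna_change"`: a list with elements
#'   `raw` (canonical string), `start_pos`, `start_offset`, `end_pos`,
#'   `end_offset` (`NA` unless a range), `edit` (one of `"substitution"`,
#'   `"duplication"`, `"deletion"`, `"insertion"`, `"delins"`), and
#'   `ref_base`/`alt_base` (substitutions only, otherwise `NA`).
#' @details Positions outside the 543-nt coding span raise a warning (not an
#'   error): registries occasionally carry 3'-UTR or legacy coordinates that
#'   should be surfaced, not rejected.
#' @examples
#' parse_cdna("c.194A>T")
#' parse_cdna("c.400+2dup")
#' parse_cdna("c.521_523del")
#' format(parse_cdna("c.81-3C>G"))
#' @seealso [parse_protein()], [classify_variant()]
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("[[:space:]]+", "", text)
  if (!startsWith(s, "c.")) {
    stop("not an HGVS cDNA description (must begin with \"c.\"): ", sQuote(text))
  }
  body <- substring(s, 3L)
  rx <- paste0(
    "^([0-9]+)([+-][0-9]+)?",             # start position, optional offset
    "(?:_([0-9]+)([+-][0-9]+)?)?",        # optional range end
    "(?:",
    "([ACGT])>([ACGT])",                  # substitution
    "|(delins)([ACGT]+)",                 # deletion-insertion
    "|(del)([ACGT]*)",                    # deletion (bases optional)
    "|(dup)([ACGT]*)",                    # duplication (bases optional)
    "|(ins)([ACGT]+)",                    # insertion
    ")$"
  )
  m <- regmatches(body, regexec(rx, body))[[1]]
  if (length(m) == 0L) {
    stop("malformed cDNA description: offending token ", sQuote(body),
         " in ", sQuote(text))
  }
  num <- function(x) if (nzchar(x)) as.integer(x) else NA_integer_
  start_pos    <- as.integer(m[2])
  start_offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  end_pos      <- num(m[4])
  end_offset   <- if (!is.na(end_pos) && nzchar(m[5])) as.integer(m[5])
                  else if (!is.na(end_pos)) 0L else NA_integer_
  ref <- NA_character_; alt <- NA_character_
  if (nzchar(m[6])) {
    edit <- "substitution"; ref <- m[6]; alt <- m[7]
    if (ref == alt) stop("substitution with identical ref and alt base: ",
                         sQuote(text))
  } else if (m[8] == "delins") { edit <- "delins";      alt <- m[9]
  } else if (m[10] == "del")   { edit <- "deletion"
  } else if (m[12] == "dup")   { edit <- "duplication"
  } else                       { edit <- "insertion";   alt <- m[15] }
  if (start_pos < 1L) stop("cDNA position must be >= 1: ", sQuote(text))
  if (!is.na(end_pos)) {
    if (end_pos < start_pos ||
        (end_pos == start_pos && end_offset < start_offset)) {
      stop("range end precedes range start in ", sQuote(text))
    }
  }
  for (p in c(start_pos, end_pos)) {
    if (!is.na(p) && p > .CDS_LENGTH) {
      warning("cDNA position ", p, " lies outside the 1..", .CDS_LENGTH,
              " coding span (", sQuote(text), ")")
    }
  }
  structure(
    list(raw = s, start_pos = start_pos, start_offset = start_offset,
         end_pos = end_pos, end_offset = end_offset, edit = edit,
         ref_base = ref, alt_base = alt),
    class = "cdna_change")
}

#' @export
format.cdna_change <- function(x, ...) {
  off <- function(o) if (is.na(o) || o == 0L) "" else sprintf("%+d", o)
  pos <- paste0(x$start_pos, off(x$start_offset))
  if (!is.na(x$end_pos)) {
    pos <- paste0(pos, "_", x$end_pos, off(x$end_offset))
  }
  tail <- switch(x$edit,
    substitution = paste0(x$ref_base, ">", x$alt_base),
    duplication  = "dup",
    deletion     = "del",
    insertion    = paste0("ins", x$alt_base),
    delins       = paste0("delins", x$alt_base))
  paste0("c.", pos, tail)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", format(x), "  [", x$edit, "]\n", sep = "")
  invisible(x)
}

#' Parse an HGVS protein description
#'
#' Parses predicted protein consequences of the forms `p.(Asp65Val)`
#' (missense), `p.(Trp98*)` (nonsense), `p.(Ala108Glufs*3)` (frameshift with
#' stop at the given downstream codon, `*?` if unknown), `p.(Phe174del)` /
#' `p.(Ser175del)` (in-frame deletion), `p.(Met1?)` (start loss) and
#' `p.(*181Argext*?)` (stop loss with unknown extension).
#'
#' @param text a single HGVS protein string of the form `"p.(...)"`.
#' @return an object of class `"protein_change"`: a list with `raw`,
#'   `ref_residue` (3-letter code, `"*"` for the stop codon), `position`
#'   (codon number), `type` (one of `"missense"`, `"nonsense"`,
#'   `"frameshift"`, `"inframe_del"`, `"start_loss"`, `"stop_loss"`),
#'   `alt_residue` (`NA` where not applicable) and `stop_distance`
#'   (frameshift only; `NA` means unknown).
#' @examples
#' parse_protein("p.(Asp65Val)")
#' parse_protein("p.(Ala108Glufs*3)")
#' parse_protein("p.(*181Argext*?)")
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("[[:space:]]+", "", text)
  if (!grepl("^p\\.\\(.+\\)$", s)) {
    stop("not an HGVS protein description (expected \"p.(...)\"): ",
         sQuote(text))
  }
  body <- sub("^p\\.\\((.+)\\)$", "\\1", s)
  aa <- "([A-Z][a-z]{2})"
  chk_aa <- function(code) {
    if (!code %in% .AA3) stop("unknown amino acid code ", sQuote(code),
                              " in ", sQuote(text))
    code
  }
  chk_pos <- function(p) {
    p <- as.integer(p)
    if (p < 1L || p > .MAX_CODON) {
      stop("codon ", p, " outside 1..", .MAX_CODON, " in ", sQuote(text))
    }
    p
  }
  out <- NULL
  if (body == "Met1?") {
    out <- list(ref_residue = "Met", position = 1L, type = "start_loss",
                alt_residue = NA_character_, stop_distance = NA_integer_)
  } else if (grepl(paste0("^\\*([0-9]+)", aa, "ext\\*(\\?|[0-9]+)$"), body)) {
    m <- regmatches(body, regexec(paste0("^\\*([0-9]+)", aa,
                                         "ext\\*(\\?|[0-9]+)$"), body))[[1]]
    out <- list(ref_residue = "*", position = chk_pos(m[2]),
                type = "stop_loss", alt_residue = chk_aa(m[3]),
                stop_distance = if (m[4] == "?") NA_integer_
                                else as.integer(m[4]))
  } else if (grepl(paste0("^", aa, "([0-9]+)", aa, "fs\\*(\\?|[0-9]+)$"),
                   body)) {
    m <- regmatches(body, regexec(paste0("^", aa, "([0-9]+)", aa,
                                         "fs\\*(\\?|[0-9]+)$"), body))[[1]]
    out <- list(ref_residue = chk_aa(m[2]), position = chk_pos(m[3]),
                type = "frameshift", alt_residue = chk_aa(m[4]),
                stop_distance = if (m[5] == "?") NA_integer_
                                else as.integer(m[5]))
  } else if (grepl(paste0("^", aa, "([0-9]+)\\*$"), body)) {
    m <- regmatches(body, regexec(paste0("^", aa, "([0-9]+)\\*$"), body))[[1]]
    out <- list(ref_residue = chk_aa(m[2]), position = chk_pos(m[3]),
                type = "nonsense", alt_residue = NA_character_,
                stop_distance = NA_integer_)
  } else if (grepl(paste0("^", aa, "([0-9]+)del$"), body)) {
    m <- regmatches(body, regexec(paste0("^", aa, "([0-9]+)del$"), body))[[1]]
    out <- list(ref_residue = chk_aa(m[2]), position = chk_pos(m[3]),
                type = "inframe_del", alt_residue = NA_character_,
                stop_distance = NA_integer_)
  } else if (grepl(paste0("^", aa, "([0-9]+)", aa, "$"), body)) {
    m <- regmatches(body, regexec(paste0("^", aa, "([0-9]+)", aa, "$"),
                                  body))[[1]]
    out <- list(ref_residue = chk_aa(m[2]), position = chk_pos(m[3]),
                type = "missense", alt_residue = chk_aa(m[4]),
                stop_distance = NA_integer_)
  } else {
    stop("malformed protein description: offending token ", sQuote(body),
         " in ", sQuote(text))
  }
  structure(c(list(raw = s), out), class = "protein_change")
}

#' @export
format.protein_change <- function(x, ...) {
  body <- switch(x$type,
    missense    = paste0(x$ref_residue, x$position, x$alt_residue),
    nonsense    = paste0(x$ref_residue, x$position, "*"),
    frameshift  = paste0(x$ref_residue, x$position, x$alt_residue, "fs*",
                         if (is.na(x$stop_distance)) "?" else x$stop_distance),
    inframe_del = paste0(x$ref_residue, x$position, "del"),
    start_loss  = paste0(x$ref_residue, x$position, "?"),
    stop_loss   = paste0("*", x$position, x$alt_residue, "ext*",
                         if (is.na(x$stop_distance)) "?" else x$stop_distance))
  paste0("p.(", body, ")")
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", format(x), "  [", x$type, "]\n", sep = "")
  invisible(x)
}

.indel_span <- function(cdna) {
  if (is.na(cdna$end_pos)) 1L else cdna$end_pos - cdna$start_pos + 1L
}

#' Classify a variant into a systematic consequence class
#'
#' Applies deterministic rules to a parsed cDNA change and (optionally) its
#' protein consequence: an intronic change within the canonical splice
#' dinucleotides (offset of absolute value 1 or 2) is `"splice_region"`;
#' otherwise the protein tag decides frameshift / nonsense / start and stop
#' loss / missense; deletions, duplications and delins with span divisible by
#' 3 (and no frameshift consequence) are `"inframe_indel"`, out-of-frame ones
#' `"frameshift"`.  Anything else (e.g. a deeper intronic substitution such as
#' `c.81-3C>G`) is `"other"`.  Published tables sometimes use looser labels
#' ("Indel" for a splice-donor duplication, "Nonsense" for a start loss); the
#' registry keeps those verbatim in a `paper_label` column while analysis
#' code uses this systematic class.
#'
#' @param cdna a [parse_cdna()] result (or the raw string).
#' @param protein a [parse_protein()] result (or raw string), or `NULL`.
#' @return a single string, one of `"missense"`, `"nonsense"`,
#'   `"frameshift"`, `"inframe_indel"`, `"start_loss"`, `"stop_loss"`,
#'   `"splice_region"`, `"other"`.
#' @examples
#' classify_variant("c.400+2dup", "p.(Ala108Glufs*3)")  # splice_region
#' classify_variant("c.194A>T", "p.(Asp65Val)")         # missense
#' classify_variant("c.81-3C>G")                        # other
#' @export
classify_variant <- function(cdna, protein = NULL) {
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  if (is.character(protein)) protein <- parse_protein(protein)
  stopifnot(inherits(cdna, "cdna_change"),
            is.null(protein) || inherits(protein, "protein_change"))
  offs <- c(cdna$start_offset,
            if (!is.na(cdna$end_pos)) cdna$end_offset else NULL)
  if (any(offs != 0L)) {
    return(if (any(abs(offs) %in% 1:2)) "splice_region" else "other")
  }
  if (!is.null(protein)) {
    cls <- switch(protein$type,
                  frameshift = "frameshift", nonsense = "nonsense",
                  start_loss = "start_loss", stop_loss = "stop_loss",
                  inframe_del = "inframe_indel", missense = "missense")
    if (!is.null(cls)) return(cls)
  }
  if (cdna$edit %in% c("deletion", "duplication", "delins", "insertion")) {
    span <- if (cdna$edit == "insertion") nchar(cdna$alt_base)
            else .indel_span(cdna)
    return(if (span %% 3L == 0L) "inframe_indel" else "frameshift")
  }
  "other"
}

#' Construct a variant record
#'
#' Bundles a cDNA change, optional protein change, gene region, optional
#' genomic position and the verbatim label used by the source table into a
#' `"variant"` object.
#'
#' @param variant_id identifier string (the cDNA description is a natural
#'   choice).
#' @param cdna HGVS cDNA string or [parse_cdna()] result.
#' @param protein HGVS protein string, [parse_protein()] result, or `NULL`.
#' @param region string like `"Exon 3"` or `"Intron 4"`; the index must lie
#'   in 1..5 (the gene has five exons), and an intronic region must agree
#'   with a nonzero intronic offset in the cDNA change.
#' @param build38_pos optional opaque genomic coordinate string
#'   `"16:<pos>"` (GRCh38); no transcript-to-genome arithmetic is performed.
#' @param paper_label optional verbatim consequence label from the source
#'   table, preserved alongside the systematic class.
#' @return an object of class `"variant"`.
#' @examples
#' v <- new_variant("c.194A>T", "c.194A>T", "p.(Asp65Val)", "Exon 3",
#'                  "16:88810550", "Missense")
#' format(v)
#' @export
new_variant <- function(variant_id, cdna, protein = NULL, region = NA,
                        build38_pos = NA, paper_label = NA) {
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  if (is.character(protein) && !is.na(protein) && nzchar(protein)) {
    protein <- parse_protein(protein)
  } else if (!inherits(protein, "protein_change")) {
    protein <- NULL
  }
  reg <- NULL
  if (!is.na(region) && nzchar(region)) {
    m <- regmatches(region, regexec("^(Exon|Intron)[[:space:]]*([0-9]+)$",
                                    region))[[1]]
    if (length(m) == 0L) stop("unparseable region: ", sQuote(region))
    idx <- as.integer(m[3])
    if (idx < 1L || idx > 5L) stop("region index ", idx, " outside 1..5")
    reg <- list(type = tolower(m[2]), index = idx)
    intronic_cdna <- cdna$start_offset != 0L
    if ((reg$type == "intron") != intronic_cdna) {
      stop("region ", sQuote(region), " inconsistent with cDNA offset in ",
           sQuote(format(cdna)))
    }
  }
  structure(
    list(variant_id = variant_id, cdna = cdna, protein = protein,
         region = reg,
         build38_pos = if (is.na(build38_pos) || !nzchar(build38_pos))
                         NA_character_ else build38_pos,
         consequence = classify_variant(cdna, protein),
         paper_label = if (is.na(paper_label)) NA_character_ else paper_label),
    class = "variant")
}

#' Format a variant for display
#'
#' Canonical display string in the house style of variant tables:
#' `"c.194A>T (p.(Asp65Val))"`, or the cDNA description alone when no
#' protein consequence is recorded.
#'
#' @param x a `"variant"` object.
#' @param ... unused.
#' @return a single string.
#' @export
format.variant <- function(x, ...) {
  if (is.null(x$protein)) format(x$cdna)
  else paste0(format(x$cdna), " (", format(x$protein), ")")
}

#' @export
print.variant <- function(x, ...) {
  reg <- if (is.null(x$region)) "" else
    paste0("  ", x$region$type, " ", x$region$index)
  cat("<variant> ", format(x), reg, "  [", x$consequence, "]\n", sep = "")
  invisible(x)
}
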