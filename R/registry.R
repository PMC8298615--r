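# Variant registry: typed storage of pathogenic variants and their allele
# counts per (database, population) cohort, with per-variant MAF and pooled
# cumulative MAF (cMAF).  All tables are plain TSV so that fixtures and
# simulator output flow through the same loaders.

.REGISTRY_COLS <- c("variant_id", "cdna", "protein", "region",
                    "build38_pos", "paper_label")
.COUNT_COLS    <- c("variant_id", "database", "population",
                    "alt_count", "allele_number")

#' Minor allele frequency from allele counts
#'
#' @param alt_count non-negative integer count of the minor (alternate)
#'   allele.
#' @param allele_number positive integer number of chromosomes genotyped
#'   (about twice the number of individuals).
#' @return `alt_count / allele_number` as a double.
#' @examples
#' maf(1299, 107928)  # ~0.012, the Icelandic founder allele
#' maf(0, 16760)      # variant absent from a cohort
#' @export
maf <- function(alt_count, allele_number) {
  if (any(allele_number <= 0)) {
    stop("allele_number must be positive (got ",
         paste(allele_number[allele_number <= 0], collapse = ", "), ")")
  }
  if (any(alt_count < 0) || any(alt_count > allele_number)) {
    stop("alt_count must satisfy 0 <= alt_count <= allele_number")
  }
  alt_count / allele_number
}

#' Read a variant registry table
#'
#' Reads a TSV with columns `variant_id`, `cdna`, `protein`, `region`,
#' `build38_pos`, `paper_label` (header required; extra columns such as
#' `genomic_ref`/`genomic_alt` are preserved) and parses every row into a
#' [new_variant()] object, reporting the offending row number on failure.
#'
#' @param path path to the TSV file.
#' @return a data.frame with an attribute `"variants"`: a named list of
#'   `"variant"` objects keyed by `variant_id`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(.REGISTRY_COLS, names(df))
  if (length(missing)) {
    stop("registry ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$variant_id)) {
    stop("duplicate variant_id in registry rows: ",
         paste(which(duplicated(df$variant_id)), collapse = ", "))
  }
  objs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    objs[[i]] <- tryCatch(
      new_variant(df$variant_id[i], df$cdna[i], df$protein[i],
                  region = df$region[i], build38_pos = df$build38_pos[i],
                  paper_label = df$paper_label[i]),
      error = function(e) stop("registry ", path, " row ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  names(objs) <- df$variant_id
  attr(df, "variants") <- objs
  df
}

#' Read an allele-count table
#'
#' Reads a TSV with columns `variant_id`, `database`, `population`,
#' `alt_count`, `allele_number` (an optional `note` column carries verbatim
#' flags about source-table inconsistencies).  Validation failures report
#' the offending row numbers.
#'
#' @param path path to the TSV file.
#' @return a data.frame with integer count columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(.COUNT_COLS, names(df))
  if (length(missing)) {
    stop("counts ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"note" %in% names(df)) df$note <- rep("", nrow(df))
  df$note[is.na(df$note)] <- ""
  df$alt_count <- as.integer(df$alt_count)
  df$allele_number <- as.integer(df$allele_number)
  validate_counts(df, where = path)
  df
}

validate_counts <- function(df, where = "counts") {
  bad_an <- which(is.na(df$allele_number) | df$allele_number <= 0L)
  if (length(bad_an)) {
    stop(where, ": allele_number must be a positive integer; bad row(s): ",
         paste(bad_an, collapse = ", "))
  }
  bad_alt <- which(is.na(df$alt_count) | df$alt_count < 0L |
                   df$alt_count > df$allele_number)
  if (length(bad_alt)) {
    stop(where, ": alt_count must satisfy 0 <= alt <= allele_number; ",
         "bad row(s): ", paste(bad_alt, collapse = ", "))
  }
  key <- paste(df$variant_id, df$database, df$population, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(where, ": duplicate (variant, database, population) row(s): ",
         paste(dup, collapse = ", "))
  }
  invisible(df)
}

#' Load a variant store from registry and counts files
#'
#' @param registry_path path to the registry TSV (see [read_registry()]).
#' @param counts_path optional path to the counts TSV (see [read_counts()]);
#'   omitted, the store carries an empty count table.
#' @return an object of class `"variant_store"` bundling the registry
#'   data.frame, the parsed `"variant"` objects and the counts data.frame.
#' @examples
#' store <- load_registry(
#'   cf_fixture("aprt_registry.tsv"),
#'   cf_fixture("table2_decode.tsv"))
#' store
#' @export
load_registry <- function(registry_path, counts_path = NULL) {
  reg <- read_registry(registry_path)
  counts <- if (is.null(counts_path)) {
    data.frame(variant_id = character(), database = character(),
               population = character(), alt_count = integer(),
               allele_number = integer(), note = character(),
               stringsAsFactors = FALSE)
  } else {
    read_counts(counts_path)
  }
  unknown <- setdiff(unique(counts$variant_id), reg$variant_id)
  if (length(unknown)) {
    warning("counts refer to variant(s) absent from the registry: ",
            paste(unknown, collapse = ", "))
  }
  structure(list(registry = reg, variants = attr(reg, "variants"),
                 counts = counts),
            class = "variant_store")
}

#' Write a variant store back to TSV files
#'
#' Inverse of [load_registry()]: `load_registry()` on the written files
#' reproduces the store (round-trip identity on the tables).
#'
#' @param store a `"variant_store"`.
#' @param registry_path,counts_path output paths; either may be `NULL` to
#'   skip that table.
#' @return the store, invisibly.
#' @export
save_registry <- function(store, registry_path = NULL, counts_path = NULL) {
  stopifnot(inherits(store, "variant_store"))
  if (!is.null(registry_path)) {
    df <- store$registry
    attr(df, "variants") <- NULL
    utils::write.table(df, registry_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(counts_path)) {
    utils::write.table(store$counts, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(store)
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store> ", nrow(x$registry), " variants, ",
      nrow(x$counts), " allele-count rows over ",
      nrow(unique(x$counts[c("database", "population")])), " cohorts\n",
      sep = "")
  invisible(x)
}

#' Cumulative minor allele frequency of one cohort
#'
#' Pools the allele counts of distinct pathogenic variants observed in a
#' single (database, population) cohort into the cumulative minor allele
#' frequency p = cMAF, the quantity entering the Hardy-Weinberg genotype
#' calculation.  Pathogenic alleles of a recessive gene are individually rare
#' and assumed never to share a haplotype, so their frequencies add.
#'
#' When all rows share one allele number AN, `p = sum(alt)/AN`.  With unequal
#' allele numbers (variants genotyped on different call sets) `p` is the sum
#' of the per-variant frequencies and the largest AN is reported as the
#' display denominator, with a `mixed_an` flag raised and a message logged.
#'
#' @param counts data.frame of count rows (columns as in [read_counts()])
#'   that must all belong to the same cohort and carry distinct variants.
#' @return an object of class `"cohort_frequency"`: list with `database`,
#'   `population`, `variant_ids`, `total_alt`, `allele_number_used`, `p`,
#'   `q = 1 - p`, `mixed_an`.
#' @examples
#' irl <- data.frame(variant_id = c("c.400+2dup", "c.541T>C"),
#'                   database = "deCODE", population = "Ireland",
#'                   alt_count = c(5L, 2L), allele_number = 2730L)
#' cmaf(irl)$p * 100  # 0.2564..., printed as 0.26%
#' @export
cmaf <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) {
    return(structure(list(database = NA_character_,
                          population = NA_character_,
                          variant_ids = character(), total_alt = 0L,
                          allele_number_used = NA_integer_,
                          p = 0, q = 1, mixed_an = FALSE),
                     class = "cohort_frequency"))
  }
  db <- unique(counts$database); pop <- unique(counts$population)
  if (length(db) > 1L || length(pop) > 1L) {
    stop("cmaf() expects counts from a single cohort; got ",
         paste(unique(paste(counts$database, counts$population)),
               collapse = " | "))
  }
  if (anyDuplicated(counts$variant_id)) {
    stop("duplicate variant_id within one cohort: ",
         paste(unique(counts$variant_id[duplicated(counts$variant_id)]),
               collapse = ", "))
  }
  validate_counts(counts)
  ans <- unique(counts$allele_number)
  mixed <- length(ans) > 1L
  if (mixed) {
    message("cmaf: mixed allele numbers in cohort ", db, " / ", pop,
            "; p is the sum of per-variant frequencies, the display ",
            "denominator is the largest allele number")
    p <- sum(counts$alt_count / counts$allele_number)
    an_used <- max(counts$allele_number)
  } else {
    an_used <- ans
    p <- sum(counts$alt_count) / an_used
  }
  structure(list(database = db, population = pop,
                 variant_ids = counts$variant_id,
                 total_alt = sum(counts$alt_count),
                 allele_number_used = an_used,
                 p = p, q = 1 - p, mixed_an = mixed),
            class = "cohort_frequency")
}

#' @export
print.cohort_frequency <- function(x, ...) {
  cat("<cohort_frequency> ", x$database, " / ", x$population, ": ",
      x$total_alt, "/", x$allele_number_used,
      if (isTRUE(x$mixed_an)) " (mixed AN)" else "",
      "  cMAF p = ", signif(x$p, 6), "\n", sep = "")
  invisible(x)
}

#' Pooled cMAF for every cohort of a store
#'
#' @param store a `"variant_store"` (or a bare counts data.frame).
#' @return a list of `"cohort_frequency"` objects, one per
#'   (database, population) cohort, in first-appearance order.
#' @export
cmaf_by_cohort <- function(store) {
  counts <- if (inherits(store, "variant_store")) store$counts else store
  key <- paste(counts$database, counts$population, sep = "\r")
  lapply(split(counts, factor(key, levels = unique(key))), cmaf)
}

#' Export registry variants as a minimal VCF
#'
#' Writes a VCF v4.2 body (CHROM 16, POS from `build38_pos`, ID =
#' `variant_id`).  REF/ALT are emitted only for registry rows that carry
#' explicit `genomic_ref` and `genomic_alt` columns; the gene lies on the
#' reverse strand and no strand complementing or transcript projection is
#' attempted, so rows without explicit genomic alleles are skipped with a
#' warning.
#'
#' @param store a `"variant_store"`.
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
write_vcf <- function(store, path) {
  stopifnot(inherits(store, "variant_store"))
  reg <- store$registry
  has_alleles <- all(c("genomic_ref", "genomic_alt") %in% names(reg))
  lines <- c("##fileformat=VCFv4.2",
             "##reference=GRCh38",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- 0L
  for (i in seq_len(nrow(reg))) {
    pos <- reg$build38_pos[i]
    ok <- !is.na(pos) && nzchar(pos) && grepl("^16:[0-9]+$", pos) &&
      has_alleles && nzchar(reg$genomic_ref[i]) && nzchar(reg$genomic_alt[i])
    if (!ok) {
      warning("skipping ", reg$variant_id[i],
              ": no explicit genomic position/alleles")
      next
    }
    lines <- c(lines, paste("16", sub("^16:", "", pos), reg$variant_id[i],
                            reg$genomic_ref[i], reg$genomic_alt[i],
                            ".", ".", ".", sep = "\t"))
    n <- n + 1L
  }
  writeLines(lines, path)
  invisible(n)
}

#' Path to a packaged fixture table
#'
#' @param name file name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return a file path (or a character vector of names).
#' @export
cf_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "carrierfreq")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("no packaged fixture ", sQuote(name), "; available: ",
         paste(list.files(dir), collapse = ", "))
  }
  path
}
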