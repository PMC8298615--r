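# Report assembly: per-cohort Hardy-Weinberg tables (pooled counts, percent
# frequency, "1 in N" figures), per-variant frequency tables across
# databases, and headline summary statistics.  Machine output (TSV/JSON)
# uses bare integers and an empty-string sentinel for unobserved cohorts so
# golden files are bit-stable; human output (markdown) uses thousands
# separators.

#' Per-cohort Hardy-Weinberg report table
#'
#' One row per (database, population) cohort: pooled alt/AN, percent cMAF,
#' and the "1 in N" homozygote and carrier figures.  Cohorts in which no
#' pathogenic allele was observed get `NA` (rendered as an empty-string
#' sentinel in TSV output), never a number.
#'
#' @param x a `"variant_store"` (per-variant counts are pooled per cohort)
#'   or a data.frame with one already-pooled row per cohort.
#' @param cohorts optional character vector of `"database / population"`
#'   labels to select, in the given order; unknown labels raise an error
#'   listing the known ones.
#' @param percent_decimals decimals for the percent column.
#' @return data.frame with columns `database`, `population`, `alt_count`,
#'   `allele_number`, `mixed_an`, `pct`, `hom_one_in`, `carrier_one_in`,
#'   `note`.
#' @examples
#' pooled <- read_counts(cf_fixture("table3_cohorts.tsv"))
#' tab <- cohort_table(pooled)
#' tab[tab$population == "Sweden", ]
#' @export
cohort_table <- function(x, cohorts = NULL, percent_decimals = 4) {
  fit <- hw_fit(x)
  e <- fit$estimates
  out <- data.frame(
    database = e$database, population = e$population,
    alt_count = e$total_alt, allele_number = e$allele_number,
    mixed_an = e$mixed_an,
    pct = percent(e$p, percent_decimals),
    hom_one_in = e$hom_one_in, carrier_one_in = e$carrier_one_in,
    note = e$note, stringsAsFactors = FALSE)
  if (!is.null(cohorts)) {
    labels <- paste(out$database, out$population, sep = " / ")
    bad <- setdiff(cohorts, labels)
    if (length(bad)) {
      stop("unknown cohort(s): ", paste(bad, collapse = ", "),
           "; known cohorts: ", paste(labels, collapse = ", "))
    }
    out <- out[match(cohorts, labels), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-population frequency table for one variant
#'
#' @param store a `"variant_store"`.
#' @param variant_id registry id of the variant.
#' @param percent_decimals decimals for the percent column.
#' @return data.frame of `(database, population, alt_count, allele_number,
#'   freq, pct)` rows in the stored (fixture) order; rows with zero counts
#'   are retained.
#' @examples
#' store <- load_registry(cf_fixture("aprt_registry.tsv"),
#'                        cf_fixture("table1_counts.tsv"))
#' variant_table(store, "c.407T>C")
#' @export
variant_table <- function(store, variant_id, percent_decimals = 2) {
  stopifnot(inherits(store, "variant_store"))
  if (!variant_id %in% store$registry$variant_id) {
    stop("unknown variant_id ", sQuote(variant_id), "; registry holds: ",
         paste(store$registry$variant_id, collapse = ", "))
  }
  rows <- store$counts[store$counts$variant_id == variant_id, , drop = FALSE]
  rows$freq <- ifelse(rows$allele_number > 0,
                      rows$alt_count / rows$allele_number, NA_real_)
  rows$pct <- percent(rows$freq, percent_decimals)
  rownames(rows) <- NULL
  rows[c("database", "population", "alt_count", "allele_number",
         "freq", "pct", "note")]
}

#' Headline summary statistics of a curated case/variant set
#'
#' Computes the counts a study of a recessive disease gene reports up
#' front: how many curated pathogenic variants there are, how many were
#' observed in at least one population database, the share of reported
#' cases with a molecular diagnosis, and the share of case alleles
#' explained by the k most common variants.
#'
#' @param case_table data.frame with columns `variant_id`, `case_alleles`
#'   (pathogenic alleles among molecularly diagnosed cases) and logical
#'   `in_databases`; an empty table yields all-zero statistics.
#' @param n_cases_total reported cases worldwide.
#' @param n_molecular cases with a molecular diagnosis.
#' @param top_k number of most common variants for the allele-share
#'   statistic.
#' @return an object of class `"summary_stats"`: list with `n_variants`,
#'   `n_in_databases`, `n_absent`, `n_cases_total`, `n_molecular`,
#'   `molecular_share_pct`, `n_case_alleles`, `top_k`, `top_k_alleles`,
#'   `top_k_allele_share`, `top_k_share_pct`.
#' @examples
#' cases <- read.delim(cf_fixture("case_alleles_synthetic.tsv"))
#' summarize_cases(cases, n_cases_total = 482, n_molecular = 311)
#' @export
summarize_cases <- function(case_table, n_cases_total = 0L,
                            n_molecular = 0L, top_k = 3L) {
  stopifnot(is.data.frame(case_table))
  if (nrow(case_table) == 0L) {
    alleles <- integer(); in_db <- logical()
  } else {
    stopifnot(all(c("variant_id", "case_alleles") %in% names(case_table)))
    alleles <- as.integer(case_table$case_alleles)
    in_db <- if ("in_databases" %in% names(case_table)) {
      as.logical(case_table$in_databases)
    } else rep(NA, nrow(case_table))
  }
  total_alleles <- sum(alleles)
  topk <- sum(sort(alleles, decreasing = TRUE)[seq_len(min(top_k,
                                                           length(alleles)))])
  share <- if (total_alleles > 0) topk / total_alleles else 0
  structure(list(
    n_variants = length(alleles),
    n_in_databases = sum(in_db, na.rm = TRUE),
    n_absent = sum(!in_db, na.rm = TRUE),
    n_cases_total = n_cases_total, n_molecular = n_molecular,
    molecular_share_pct = if (n_cases_total > 0)
      percent(n_molecular / n_cases_total, 1) else 0,
    n_case_alleles = total_alleles,
    top_k = as.integer(top_k), top_k_alleles = topk,
    top_k_allele_share = share,
    top_k_share_pct = percent(share, 1)),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Curated pathogenic variant set\n",
      sprintf("  %d variants: %d observed in population databases, %d absent\n",
              x$n_variants, x$n_in_databases, x$n_absent),
      sprintf("  %d reported cases, %d (%.1f%%) with molecular diagnosis\n",
              x$n_cases_total, x$n_molecular, x$molecular_share_pct),
      sprintf("  top %d variants carry %d/%d (%.1f%%) of case alleles\n",
              x$top_k, x$top_k_alleles, x$n_case_alleles,
              x$top_k_share_pct), sep = "")
  invisible(x)
}

#' Write the full report to an output directory
#'
#' Produces `report.tsv` (machine-readable cohort table: bare integers,
#' empty-string sentinels), `report.md` (human-readable markdown with
#' thousands separators) and, when a case table is supplied,
#' `summary.json` with the [summarize_cases()] statistics.
#'
#' @param x input accepted by [cohort_table()].
#' @param out_dir output directory (created if absent).
#' @param case_table optional case-allele data.frame for the summary.
#' @param n_cases_total,n_molecular passed to [summarize_cases()].
#' @param percent_decimals decimals for the percent column.
#' @return invisibly, the paths written.
#' @export
write_report <- function(x, out_dir, case_table = NULL,
                         n_cases_total = 0L, n_molecular = 0L,
                         percent_decimals = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort_table(x, percent_decimals = percent_decimals)
  machine <- tab
  machine$hom_one_in <- ifelse(is.na(tab$hom_one_in), "",
                               sprintf("%.0f", tab$hom_one_in))
  machine$carrier_one_in <- ifelse(is.na(tab$carrier_one_in), "",
                                   sprintf("%.0f", tab$carrier_one_in))
  tsv <- file.path(out_dir, "report.tsv")
  utils::write.table(machine, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- file.path(out_dir, "report.md")
  lines <- c(
    "| Cohort | Allele count | Allele frequency (%) | Homozygotes (1 in) | Carriers (1 in) |",
    "|---|---|---|---|---|",
    sprintf("| %s / %s | %s | %s | %s | %s |",
            tab$database, tab$population,
            paste0(tab$alt_count, "/",
                   formatC(tab$allele_number, format = "d", big.mark = ",")),
            tab$pct,
            ifelse(is.na(tab$hom_one_in), "not observed",
                   formatC(tab$hom_one_in, format = "d", big.mark = ",")),
            ifelse(is.na(tab$carrier_one_in), "not observed",
                   formatC(tab$carrier_one_in, format = "d",
                           big.mark = ","))))
  writeLines(lines, md)
  paths <- c(tsv, md)
  if (!is.null(case_table)) {
    st <- summarize_cases(case_table, n_cases_total, n_molecular)
    js <- file.path(out_dir, "summary.json")
    jsonlite::write_json(unclass(st), js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}

#' Read a run configuration file
#'
#' JSON with optional keys `population_sizes` (label to individuals),
#' `percent_decimals`, `rounding_mode` (only `"half_away"` is supported),
#' `cases` (`total`, `molecular`) and `seed`.
#'
#' @param path path to the JSON file.
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$rounding_mode) && cfg$rounding_mode != "half_away") {
    stop("unsupported rounding_mode ", sQuote(cfg$rounding_mode),
         "; only \"half_away\" is implemented")
  }
  if (!is.null(cfg$population_sizes) &&
      any(unlist(cfg$population_sizes) <= 0)) {
    stop("population sizes must be positive")
  }
  cfg$percent_decimals <- cfg$percent_decimals %||% 4
  cfg$rounding_mode <- "half_away"
  cfg
}
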