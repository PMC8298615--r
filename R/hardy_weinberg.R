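# Hardy-Weinberg genotype-frequency mathematics for a recessive disease gene.
#
# The model: let p be the cumulative minor allele frequency (cMAF) of all
# pathogenic alleles of the gene in a cohort and q = 1 - p.  Under random
# mating the genotype classes have frequencies p^2 (two pathogenic alleles:
# homozygotes *and* compound heterozygotes, since pathogenic alleles never
# share a haplotype), 2pq (carriers) and q^2 (reference homozygotes).  The
# reporting conventions of the field — percent allele frequency, "1 in N"
# reciprocals, expected case counts — are all derived from the exact integer
# allele counts, never from pre-rounded percentages.

#' Hardy-Weinberg genotype frequencies
#'
#' @param p pathogenic allele frequency (the cohort cMAF), in `[0, 1]`.
#' @return named numeric vector `c(hom_alt = p^2, het = 2*p*(1-p),
#'   hom_ref = (1-p)^2)`; the three entries sum to 1.  `hom_alt` is the
#'   frequency of biallelic (affected) genotypes, including compound
#'   heterozygotes under the no-shared-haplotype assumption.
#' @examples
#' genotype_frequencies(7 / 2730)["hom_alt"]  # 1/152100
#' genotype_frequencies(0.5)
#' @export
genotype_frequencies <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, !is.na(p))
  if (p < 0 || p > 1) stop("allele frequency p must lie in [0, 1], got ", p)
  q <- 1 - p
  c(hom_alt = p^2, het = 2 * p * q, hom_ref = q^2)
}

.check_alt_an <- function(alt, an) {
  stopifnot(is.numeric(alt), is.numeric(an),
            length(an) %in% c(1L, length(alt)))
  if (any(an <= 0)) stop("allele_number must be positive")
  if (any(alt < 0 | alt > an)) stop("need 0 <= alt <= allele_number")
}

#' Expected "1 in N" homozygote frequency from allele counts
#'
#' The reciprocal of the biallelic genotype frequency p^2, with p taken as
#' the exact ratio `alt/an`, rounded half away from zero to an integer —
#' the convention of published cohort tables.  Variants not observed in the
#' cohort (`alt = 0`) have no finite reciprocal and yield the "not observed"
#' sentinel `NA` rather than a number.
#'
#' @param alt pooled pathogenic allele count (vectorised).
#' @param an allele number (chromosomes genotyped).
#' @return numeric vector of N such that the expected homozygote frequency
#'   is "1 in N"; `NA` where `alt = 0`.
#' @examples
#' one_in_homozygote(7, 2730)    # 152100
#' one_in_homozygote(3, 6306)    # 4418404
#' one_in_homozygote(0, 1000)    # NA: not observed
#' @export
one_in_homozygote <- function(alt, an) {
  .check_alt_an(alt, an)
  ifelse(alt == 0, NA_real_, round_half_away((an / alt)^2))
}

#' Expected "1 in N" carrier frequency from allele counts
#'
#' Reciprocal of the heterozygous-carrier frequency 2pq with p the exact
#' ratio `alt/an`, rounded half away from zero.  `alt = 0` yields the
#' "not observed" sentinel `NA`; `alt = an` (p = 1, so 2pq = 0) is a domain
#' error.
#'
#' @inheritParams one_in_homozygote
#' @return numeric vector of N ("1 carrier in N individuals").
#' @examples
#' one_in_carrier(12, 17662)   # 736
#' one_in_carrier(9, 24940)    # 1386
#' @export
one_in_carrier <- function(alt, an) {
  .check_alt_an(alt, an)
  if (any(alt == an)) {
    stop("p = 1: the carrier class 2pq is empty, no finite reciprocal")
  }
  p <- alt / an
  ifelse(alt == 0, NA_real_, round_half_away(1 / (2 * p * (1 - p))))
}

#' Expected number of affected (biallelic) individuals in a population
#'
#' `population_size * p^2`, unrounded: presentation rounding (significant
#' figures for headline projections) is left to the caller.
#'
#' @param p pathogenic allele frequency (cMAF) in `[0, 1]`.
#' @param population_size number of individuals in the projection
#'   population.
#' @return expected count of biallelic individuals (a real number).
#' @examples
#' expected_cases(0.0005, 2e7)        # 5 expected cases
#' expected_cases(1304 / 107928, 360000)  # ~53 in a founder population
#' @export
expected_cases <- function(p, population_size) {
  stopifnot(is.numeric(p), is.numeric(population_size),
            all(population_size > 0))
  if (any(p < 0 | p > 1)) stop("allele frequency p must lie in [0, 1]")
  population_size * p^2
}

#' Fit Hardy-Weinberg genotype frequencies to cohort allele counts
#'
#' The central estimator of the package.  For each (database, population)
#' cohort it pools the counts of the distinct pathogenic variants into the
#' cumulative minor allele frequency p (see [cmaf()]) and derives the
#' Hardy-Weinberg genotype-class frequencies, together with the "1 in N"
#' homozygote and carrier reporting figures computed from the exact counts.
#'
#' @param x a `"variant_store"` from [load_registry()], or a counts
#'   data.frame (per-variant rows as in [read_counts()], or already-pooled
#'   rows carrying one row per cohort), or a numeric `alt` count (with `an`
#'   given) for a single anonymous cohort.
#' @param an allele number, only when `x` is a bare numeric alt count.
#' @param pooled logical; set `TRUE` when `x` holds one pre-pooled row per
#'   cohort (no variant accounting is done then).  Defaults to `TRUE`
#'   exactly when `x` has no `variant_id` column.
#' @param ... unused.
#' @return an object of class `"hw_fit"`: a list with
#'   \describe{
#'     \item{estimates}{data.frame, one row per cohort: `database`,
#'       `population`, `total_alt`, `allele_number`, `mixed_an`, `p`, `q`,
#'       `f_biallelic` (p^2), `f_carrier` (2pq), `f_ref` (q^2),
#'       `hom_one_in`, `carrier_one_in`, `note`.}
#'     \item{variant_freqs}{per-cohort named vectors of per-variant MAFs
#'       (empty for pooled input), used by [simulate.hw_fit()].}
#'     \item{call}{the matched call.}
#'   }
#'   Methods: [print.hw_fit()], [summary.hw_fit()], `coef()` (the per-cohort
#'   p), [predict.hw_fit()] (expected affected/carrier counts),
#'   [simulate.hw_fit()] (forward cohort simulation), `plot()`.
#' @examples
#' fit <- hw_fit(7, an = 2730)   # pooled Irish pathogenic alleles
#' fit
#' coef(fit)                     # cMAF 0.002564...
#' predict(fit, population_size = 4.9e6)   # ~32 expected cases
#' @export
hw_fit <- function(x, an = NULL, pooled = NULL, ...) {
  cl <- match.call()
  if (is.numeric(x)) {
    stopifnot(!is.null(an), length(x) == length(an))
    counts <- data.frame(database = "(data)", population = "(cohort)",
                         alt_count = as.integer(x),
                         allele_number = as.integer(an),
                         note = "", stringsAsFactors = FALSE)
    pooled <- TRUE
  } else if (inherits(x, "variant_store")) {
    counts <- x$counts
    if (is.null(pooled)) pooled <- FALSE
  } else if (is.data.frame(x)) {
    counts <- x
    if (is.null(pooled)) pooled <- !("variant_id" %in% names(counts))
  } else {
    stop("x must be a variant_store, a counts data.frame or an alt count")
  }
  if (!"note" %in% names(counts)) counts$note <- ""
  if (!"database" %in% names(counts)) counts$database <- "(data)"
  if (!"population" %in% names(counts)) counts$population <- "(cohort)"

  if (pooled) {
    freqs <- lapply(seq_len(nrow(counts)), function(i) {
      row <- counts[i, ]
      structure(list(database = row$database, population = row$population,
                     variant_ids = character(),
                     total_alt = row$alt_count,
                     allele_number_used = row$allele_number,
                     p = row$alt_count / row$allele_number,
                     q = 1 - row$alt_count / row$allele_number,
                     mixed_an = FALSE),
                class = "cohort_frequency")
    })
    notes <- counts$note
    vfreqs <- rep(list(numeric()), nrow(counts))
  } else {
    freqs <- cmaf_by_cohort(counts)
    notes <- vapply(freqs, function(f) {
      idx <- counts$database == f$database & counts$population == f$population
      paste(unique(counts$note[idx][nzchar(counts$note[idx])]),
            collapse = "; ")
    }, character(1))
    vfreqs <- lapply(freqs, function(f) {
      idx <- counts$database == f$database & counts$population == f$population
      stats::setNames(counts$alt_count[idx] / counts$allele_number[idx],
                      counts$variant_id[idx])
    })
  }
  est <- do.call(rbind, lapply(seq_along(freqs), function(i) {
    f <- freqs[[i]]
    g <- genotype_frequencies(f$p)
    data.frame(
      database = f$database, population = f$population,
      total_alt = f$total_alt, allele_number = f$allele_number_used,
      mixed_an = f$mixed_an, p = f$p, q = f$q,
      f_biallelic = g[["hom_alt"]], f_carrier = g[["het"]],
      f_ref = g[["hom_ref"]],
      hom_one_in = if (f$total_alt > 0)
        one_in_homozygote(f$total_alt, f$allele_number_used) else NA_real_,
      carrier_one_in = if (f$total_alt > 0 &&
                           f$total_alt < f$allele_number_used)
        one_in_carrier(f$total_alt, f$allele_number_used) else NA_real_,
      note = notes[i], stringsAsFactors = FALSE)
  }))
  rownames(est) <- NULL
  if (any(est$p > 0.5)) {
    warning("cohort(s) with p > 0.5: pooled allele is not a minor allele")
  }
  # mixed-AN cohorts: the 1-in figures must come from p itself, not from the
  # display ratio total_alt/allele_number
  mix <- which(est$mixed_an & est$p > 0 & est$p < 1)
  if (length(mix)) {
    est$hom_one_in[mix] <- round_half_away(1 / est$p[mix]^2)
    est$carrier_one_in[mix] <-
      round_half_away(1 / (2 * est$p[mix] * est$q[mix]))
  }
  names(vfreqs) <- paste(est$database, est$population, sep = " / ")
  structure(list(estimates = est, variant_freqs = vfreqs, call = cl),
            class = "hw_fit")
}

#' @describeIn hw_fit compact console display of the fitted cohorts.
#' @export
print.hw_fit <- function(x, digits = 4, ...) {
  cat("Hardy-Weinberg genotype frequencies from pooled allele counts\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  e <- x$estimates
  out <- data.frame(
    cohort = paste(e$database, e$population, sep = " / "),
    `alt/AN` = paste0(e$total_alt, "/", e$allele_number,
                      ifelse(e$mixed_an, "*", "")),
    `cMAF %` = percent(e$p, digits),
    `biallelic` = format_one_in(e$hom_one_in),
    `carrier` = format_one_in(e$carrier_one_in),
    check.names = FALSE)
  print(out, row.names = FALSE, right = FALSE)
  if (any(e$mixed_an)) {
    cat("* mixed allele numbers: p is the sum of per-variant frequencies\n")
  }
  invisible(x)
}

#' @export
coef.hw_fit <- function(object, ...) {
  stats::setNames(object$estimates$p,
                  paste(object$estimates$database,
                        object$estimates$population, sep = " / "))
}

#' Summarise a Hardy-Weinberg fit
#'
#' @param object an `"hw_fit"`.
#' @param percent_decimals decimals for the percent cMAF column.
#' @param ... unused.
#' @return a `"summary.hw_fit"`: the estimates plus display columns
#'   (`pct`, formatted 1-in strings) and any source-table notes.
#' @export
summary.hw_fit <- function(object, percent_decimals = 4, ...) {
  e <- object$estimates
  e$pct <- percent(e$p, percent_decimals)
  e$hom_display <- format_one_in(e$hom_one_in)
  e$carrier_display <- format_one_in(e$carrier_one_in)
  structure(list(table = e, call = object$call), class = "summary.hw_fit")
}

#' @export
print.summary.hw_fit <- function(x, ...) {
  cat("Hardy-Weinberg fit summary\nCall: ", deparse(x$call), "\n\n", sep = "")
  e <- x$table
  print(data.frame(cohort = paste(e$database, e$population, sep = " / "),
                   alt = e$total_alt, AN = e$allele_number, pct = e$pct,
                   biallelic = e$hom_display, carrier = e$carrier_display,
                   note = e$note, check.names = FALSE),
        row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Predict expected genotype counts in a projection population
#'
#' @param object an `"hw_fit"`.
#' @param population_size numeric; either one value applied to every cohort
#'   or a vector named by `"database / population"` cohort labels.
#' @param what `"affected"` (biallelic, `N * p^2`) or `"carriers"`
#'   (`N * 2pq`).
#' @param ... unused.
#' @return named numeric vector of expected counts, unrounded.
#' @examples
#' fit <- hw_fit(7, an = 2730)
#' predict(fit, population_size = 4.9e6)  # ~32 biallelic individuals
#' @export
predict.hw_fit <- function(object, population_size,
                           what = c("affected", "carriers"), ...) {
  what <- match.arg(what)
  e <- object$estimates
  labels <- paste(e$database, e$population, sep = " / ")
  n <- if (length(population_size) == 1L && is.null(names(population_size))) {
    rep(population_size, nrow(e))
  } else {
    if (!all(labels %in% names(population_size))) {
      stop("population_size must name every cohort: ",
           paste(setdiff(labels, names(population_size)), collapse = ", "))
    }
    unname(population_size[labels])
  }
  out <- switch(what,
                affected = expected_cases(e$p, n),
                carriers = n * e$f_carrier)
  stats::setNames(out, labels)
}

#' @describeIn hw_fit barplot of per-cohort percent cMAF.
#' @param y unused.
#' @export
plot.hw_fit <- function(x, y, ...) {
  e <- x$estimates
  graphics::barplot(100 * e$p,
                    names.arg = paste(e$database, e$population, sep = "\n"),
                    ylab = "cMAF (%)", las = 2, cex.names = 0.7, ...)
  invisible(x)
}

#' Simulate cohorts from a Hardy-Weinberg fit
#'
#' Draws diploid cohorts with the fitted per-variant allele frequencies as
#' truth (per-variant frequencies are available when the fit was made from
#' per-variant counts; pooled fits simulate a single pooled pathogenic
#' allele, which leaves the biallelic and carrier class frequencies
#' unchanged).
#'
#' @param object an `"hw_fit"`.
#' @param nsim number of replicate cohorts.
#' @param seed integer seed (required, for replayability).
#' @param n_individuals diploid individuals per cohort; default is half the
#'   fitted allele number.
#' @param ... unused.
#' @return a list of `nsim` [simulate_cohort()] results.
#' @export
simulate.hw_fit <- function(object, nsim = 1, seed = 1,
                            n_individuals = NULL, ...) {
  e <- object$estimates
  pops <- lapply(seq_len(nrow(e)), function(i) {
    freqs <- object$variant_freqs[[i]]
    if (!length(freqs)) freqs <- stats::setNames(e$p[i], "pooled")
    n <- if (is.null(n_individuals)) ceiling(e$allele_number[i] / 2)
         else n_individuals
    list(label = paste(e$database[i], e$population[i], sep = " / "),
         n = n, freqs = freqs)
  })
  lapply(seq_len(nsim), function(k) {
    simulate_cohort(sim_scenario(pops, seed = seed + k - 1L))
  })
}
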