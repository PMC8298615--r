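# Forward simulation of database-style cohorts under Hardy-Weinberg
# equilibrium.  Each diploid individual receives two chromosomes drawn
# independently from the categorical distribution {reference: 1 - sum(p_i),
# pathogenic variant i: p_i}; because at most one pathogenic allele can sit
# on a chromosome, the per-population pathogenic frequencies must sum to at
# most 1.  The simulator is the independent oracle for the Hardy-Weinberg
# estimator: realized biallelic fractions converge to (cMAF)^2 and carrier
# fractions to 2pq.
#
# Randomness comes from R's default Mersenne-Twister stream seeded once per
# scenario, so a (scenario, seed) pair reproduces a cohort exactly.

#' Define a simulation scenario
#'
#' @param populations list of populations, each a list with `label`
#'   (string), `n` (diploid individuals) and `freqs` (named numeric vector
#'   of true per-variant allele frequencies; the names become variant ids).
#' @param seed integer seed controlling all draws.
#' @param founder_label optional label of a population carrying a
#'   high-frequency founder allele (documentation only; no behaviour
#'   change).
#' @return an object of class `"sim_scenario"`.
#' @examples
#' sc <- sim_scenario(list(list(label = "isolate", n = 1000,
#'                              freqs = c(v1 = 0.01))), seed = 7)
#' @export
sim_scenario <- function(populations, seed, founder_label = NULL) {
  stopifnot(is.list(populations), length(populations) >= 1L,
            is.numeric(seed), length(seed) == 1L)
  for (pop in populations) {
    stopifnot(is.character(pop$label), pop$n >= 1L,
              is.numeric(pop$freqs), length(pop$freqs) >= 1L,
              !is.null(names(pop$freqs)))
    if (any(pop$freqs < 0)) stop("negative allele frequency in ", pop$label)
    if (sum(pop$freqs) > 1) {
      stop("population ", pop$label, ": pathogenic allele frequencies sum ",
           "to ", sum(pop$freqs), " > 1; at most one pathogenic allele ",
           "can occupy a chromosome")
    }
  }
  structure(list(populations = populations, seed = as.integer(seed),
                 founder_label = founder_label),
            class = "sim_scenario")
}

#' Shipped scenario presets
#'
#' * `"iceland_founder"` — a founder population of 50,000 diploids with one
#'   pathogenic allele at frequency 0.012, plus a mainland population of
#'   7452 diploids carrying the same allele 100 times rarer (1.2e-4).
#' * `"ireland"` — 1365 diploids (2730 chromosomes) with three pathogenic
#'   variants at 5, 1 and 1 copies per 2730 chromosomes.
#' * `"null"` — 1000 diploids, one pathogenic allele at frequency 0.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a `"sim_scenario"`.
#' @export
sim_preset <- function(name = c("iceland_founder", "ireland", "null"),
                       seed = 1) {
  name <- match.arg(name)
  pops <- switch(name,
    iceland_founder = list(
      list(label = "founder_isolate", n = 50000L,
           freqs = c(founder_missense = 0.012)),
      list(label = "mainland", n = 7452L,
           freqs = c(founder_missense = 0.00012))),
    ireland = list(
      list(label = "ireland", n = 1365L,
           freqs = c(splice_dup = 5 / 2730, stop_loss = 1 / 2730,
                     other = 1 / 2730))),
    null = list(
      list(label = "null", n = 1000L, freqs = c(absent = 0))))
  sim_scenario(pops, seed = seed,
               founder_label = if (name == "iceland_founder")
                 "founder_isolate" else NULL)
}

#' Simulate a diploid cohort
#'
#' Draws every individual's two chromosomes independently from the
#' categorical allele distribution of its population and tallies genotype
#' classes, emitting an allele-count table in the standard counts schema so
#' simulated cohorts flow through [cmaf()] / [hw_fit()] unchanged.
#'
#' @param scenario a [sim_scenario()].
#' @return an object of class `"sim_cohort"`: list with
#'   \describe{
#'     \item{scenario}{the input scenario.}
#'     \item{counts}{data.frame `(variant_id, database = "simulated",
#'       population, alt_count, allele_number)`.}
#'     \item{tallies}{per-population list: `n` individuals, `n_hom` (named,
#'       per variant), `n_compound_het`, `n_biallelic`
#'       (`= sum(n_hom) + n_compound_het`), `n_carrier` (exactly one
#'       pathogenic allele), `n_ref`, and `realized_cmaf`.}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_preset("ireland", seed = 42))
#' sim$counts
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  counts <- NULL
  tallies <- list()
  for (pop in scenario$populations) {
    k <- length(pop$freqs)
    n <- as.integer(pop$n)
    pr <- c(1 - sum(pop$freqs), pop$freqs)
    # category 1 = reference, categories 2..k+1 = pathogenic variants
    draw <- sample.int(k + 1L, size = 2L * n, replace = TRUE, prob = pr)
    a1 <- draw[seq_len(n)]
    a2 <- draw[n + seq_len(n)]
    alt <- tabulate(draw - 1L, nbins = k)       # per-variant allele counts
    path1 <- a1 > 1L; path2 <- a2 > 1L
    n_hom <- vapply(seq_len(k) + 1L,
                    function(j) sum(a1 == j & a2 == j), integer(1))
    names(n_hom) <- names(pop$freqs)
    n_biallelic <- sum(path1 & path2)
    n_compound_het <- n_biallelic - sum(n_hom)
    n_carrier <- sum(xor(path1, path2))
    counts <- rbind(counts, data.frame(
      variant_id = names(pop$freqs), database = "simulated",
      population = pop$label, alt_count = alt,
      allele_number = 2L * n, note = "", stringsAsFactors = FALSE))
    tallies[[pop$label]] <- list(
      n = n, n_hom = n_hom, n_compound_het = n_compound_het,
      n_biallelic = n_biallelic, n_carrier = n_carrier,
      n_ref = n - n_biallelic - n_carrier,
      realized_cmaf = sum(alt) / (2 * n))
  }
  rownames(counts) <- NULL
  structure(list(scenario = scenario, counts = counts, tallies = tallies),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> seed ", x$scenario$seed, "\n", sep = "")
  for (lbl in names(x$tallies)) {
    t <- x$tallies[[lbl]]
    cat(sprintf("  %s: n = %d, biallelic %d (hom %d + cmpd het %d), %s\n",
                lbl, t$n, t$n_biallelic, sum(t$n_hom), t$n_compound_het,
                sprintf("carriers %d, realized cMAF %.3g",
                        t$n_carrier, t$realized_cmaf)))
  }
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' @param sim a `"sim_cohort"`.
#' @param counts_path TSV path for the allele-count table (standard counts
#'   schema).
#' @param tallies_path optional JSON path for the genotype tallies.
#' @return `sim`, invisibly.
#' @export
write_sim_cohort <- function(sim, counts_path, tallies_path = NULL) {
  stopifnot(inherits(sim, "sim_cohort"))
  utils::write.table(sim$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tallies_path)) {
    jsonlite::write_json(c(list(seed = sim$scenario$seed), sim$tallies),
                         tallies_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(sim)
}

#' Parameter-recovery check for the Hardy-Weinberg estimator
#'
#' Replicates [simulate_cohort()] over a set of seeds and tests, per
#' population, that (a) the mean realized biallelic fraction lies within 3
#' Monte-Carlo standard errors of the Hardy-Weinberg prediction p^2 (p the
#' true cMAF) and (b) the per-replicate realized cMAF lies within 3 binomial
#' standard errors of the truth in all but a small number of replicates.
#' With a 3-SE band about 0.27% of correct replicates fall outside by
#' chance, so the allowed number of outliers is the upper 99.9% Poisson
#' quantile of `replicates * P(|Z| > 3)` rather than zero.
#'
#' @param scenario a `"sim_scenario"`; its `seed` is ignored in favour of
#'   `seeds`.
#' @param replicates number of replicate cohorts.
#' @param seeds integer vector of seeds, default `seq_len(replicates)`.
#' @return an object of class `"recovery_check"`: per-population list with
#'   `true_p`, `predicted_biallelic` (p^2), `mean_biallelic`, `mc_se`,
#'   `mean_within_3se`, `n_cmaf_outside_3se`, `max_outside_allowed`,
#'   `total_biallelic` (pooled over replicates, for very rare scenarios
#'   where per-replicate counts are typically 0), `pass`; plus an overall
#'   `pass` attribute.
#' @examples
#' rc <- recovery_check(sim_preset("ireland"), replicates = 20)
#' rc$populations$ireland$pass
#' @export
recovery_check <- function(scenario, replicates = 200,
                           seeds = seq_len(replicates)) {
  stopifnot(inherits(scenario, "sim_scenario"), length(seeds) == replicates)
  labels <- vapply(scenario$populations, `[[`, "", "label")
  biallelic <- matrix(0, nrow = replicates, ncol = length(labels),
                      dimnames = list(NULL, labels))
  cmaf_hat <- biallelic
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc$seed <- as.integer(seeds[r])
    sim <- simulate_cohort(sc)
    for (lbl in labels) {
      biallelic[r, lbl] <- sim$tallies[[lbl]]$n_biallelic
      cmaf_hat[r, lbl] <- sim$tallies[[lbl]]$realized_cmaf
    }
  }
  p_out <- 2 * stats::pnorm(-3)
  max_outside <- stats::qpois(0.999, lambda = replicates * p_out)
  pops <- list()
  for (i in seq_along(labels)) {
    pop <- scenario$populations[[i]]
    p <- sum(pop$freqs)
    n <- pop$n
    pred <- p^2
    frac <- biallelic[, i] / n
    mc_se <- sqrt(pred * (1 - pred) / (n * replicates))
    mean_ok <- if (mc_se == 0) mean(frac) == pred
               else abs(mean(frac) - pred) <= 3 * mc_se
    se_cmaf <- sqrt(p * (1 - p) / (2 * n))
    outside <- if (se_cmaf == 0) sum(cmaf_hat[, i] != p)
               else sum(abs(cmaf_hat[, i] - p) > 3 * se_cmaf)
    pops[[labels[i]]] <- list(
      true_p = p, predicted_biallelic = pred,
      mean_biallelic = mean(frac), mc_se = mc_se,
      mean_within_3se = mean_ok,
      n_cmaf_outside_3se = outside, max_outside_allowed = max_outside,
      total_biallelic = sum(biallelic[, i]),
      expected_total_biallelic = pred * n * replicates,
      pass = mean_ok && outside <= max_outside)
  }
  structure(list(populations = pops, replicates = replicates,
                 pass = all(vapply(pops, `[[`, TRUE, "pass"))),
            class = "recovery_check")
}

#' @export
print.recovery_check <- function(x, ...) {
  cat("Parameter recovery over ", x$replicates, " replicate cohorts\n",
      sep = "")
  for (lbl in names(x$populations)) {
    p <- x$populations[[lbl]]
    cat(sprintf(
      "  %s: true p^2 = %.4g, mean realized %.4g (MC SE %.2g) %s; %s\n",
      lbl, p$predicted_biallelic, p$mean_biallelic, p$mc_se,
      if (p$mean_within_3se) "ok" else "OUTSIDE 3 SE",
      sprintf("cMAF outliers %d/%d (allowed %d)", p$n_cmaf_outside_3se,
              x$replicates, p$max_outside_allowed)))
  }
  cat(if (x$pass) "PASS\n" else "FAIL\n")
  invisible(x)
}
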