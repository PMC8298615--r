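# Independent brute-force oracle for the "1 in N" figures: enumerate every
# ordered pair of chromosomes drawn (with replacement, i.e. random mating)
# from a pool of `an` chromosomes of which `alt` carry the pathogenic
# allele, count the genotype classes, and take the rounded reciprocal.
# Deliberately shares no code with the package (its own rounding included).
oracle_one_in <- function(alt, an, what = c("hom", "carrier")) {
  what <- match.arg(what)
  pool <- c(rep(1L, alt), rep(0L, an - alt))
  hom <- 0L; het <- 0L
  for (i in seq_len(an)) {
    for (j in seq_len(an)) {
      if (pool[i] == 1L && pool[j] == 1L) hom <- hom + 1L
      else if (pool[i] != pool[j]) het <- het + 1L
    }
  }
  total <- as.numeric(an) * an
  x <- if (what == "hom") total / hom else total / het
  floor(x + 0.5)   # half away from zero (x > 0 here)
}

# variant strings printed in the source tables (per-variant frequency table
# and the full sequenced-cohort table), used for round-trip identity checks
table_cdna_strings <- c(
  "c.194A>T", "c.1A>C", "c.329T>C", "c.400+2dup", "c.521_523del",
  "c.541T>C", "c.250G>A", "c.407T>C")
table_protein_strings <- c(
  "p.(Asp65Val)", "p.(Met1?)", "p.(Leu110Pro)", "p.(Ala108Glufs*3)",
  "p.(Phe174del)", "p.(*181Argext*?)", "p.(Val84Met)", "p.(Met136Thr)")
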