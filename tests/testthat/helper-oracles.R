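# Shared helpers and independent oracles used across the suite.

# Brute-force Mendelian gamete oracle for a two-locus genotype: enumerates
# the four meiotic products directly from the recombination fraction,
# independent of the package's pattern-enumeration code path.
mendelian_two_locus_oracle <- function(h1, h2, r) {
  out <- c(stats::setNames((1 - r) / 2, paste(h1[1], h1[2], sep = ":")),
           stats::setNames(r / 2, paste(h1[1], h2[2], sep = ":")),
           stats::setNames(r / 2, paste(h2[1], h1[2], sep = ":")),
           stats::setNames((1 - r) / 2, paste(h2[1], h2[2], sep = ":")))
  s <- tapply(out, names(out), sum)
  s <- s[s > 0]
  stats::setNames(as.numeric(s), names(s))
}

# Expected allele frequency among gametes, from a gamete distribution.
gamete_allele_freq <- function(gd, locus, allele) {
  haps <- strsplit(names(gd), ":", fixed = TRUE)
  sum(gd[vapply(haps, function(h) h[locus] == allele, logical(1))])
}

# Single-sex Hardy-Weinberg oracle for a recessive lethal (no editing):
# genotypes at hatchling in HW proportions, homozygotes die before
# reproducing, gametes recounted.  q' = q / (1 + q).
recessive_lethal_oracle <- function(q) {
  x <- c(WW = (1 - q)^2, WG = 2 * q * (1 - q), GG = q^2)
  x["GG"] <- 0                      # homozygote lethality
  x <- x / sum(x)
  unname(x["WG"] / 2)               # construct frequency among gametes
}

# Male-pool allele frequency trajectory computed through the public
# step_population() interface (used for the self-limiting property).
male_allele_frequency <- function(strategy, allele_match, init, lc,
                                  generations) {
  counts <- init
  freq <- numeric(generations + 1L)
  male_freq <- function(counts) {
    keys <- names(counts)[counts > 0]
    keys <- keys[endsWith(keys, "|M")]
    tot <- 0; hit <- 0
    for (k in keys) {
      body <- sub("[|]M$", "", k)
      alleles <- unlist(strsplit(strsplit(body, "/", fixed = TRUE)[[1]],
                                 ":", fixed = TRUE))
      tot <- tot + length(alleles) * counts[[k]]
      hit <- hit + sum(alleles %in% allele_match) * counts[[k]]
    }
    if (tot == 0) NA_real_ else hit / tot
  }
  freq[1] <- male_freq(counts)
  for (t in seq_len(generations)) {
    counts <- step_population(counts, strategy, lc)
    counts <- counts[counts > 0]
    freq[t + 1L] <- male_freq(counts)
  }
  freq
}

suppression_achieved <- function(sim) {
  1 - min(sim$series$females_rel[-1]) / sim$lc$F0
}
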