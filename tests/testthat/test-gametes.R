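test_that("germline editing in heterozygotes follows the editor's state", {
  s <- make_strategy("pdne1")
  # full editing: the wild-type gamete always becomes a dominant edit
  gd <- gamete_distribution("G/W|M", s$arch, s$params)
  expect_equal(gd[order(names(gd))], c(E_dom = 0.5, G = 0.5))
  # no editing
  gd0 <- gamete_distribution("G/W|M", s$arch,
                             override_params(s$params, list(u = 0)))
  expect_equal(gd0[order(names(gd0))], c(G = 0.5, W = 0.5))
  # editing requires both components: a gRNA-dead construct cannot edit
  gdg <- gamete_distribution("G_dgRNA/W|F", s$arch, s$params)
  expect_equal(gdg[order(names(gdg))], c(G_dgRNA = 0.5, W = 0.5))
  # ... and neither can a Cas9-dead or doubly dead one
  for (a in c("G_dCas9", "G_dBoth")) {
    gdx <- gamete_distribution(paste0(a, "/W|F"), s$arch, s$params)
    expect_equal(sort(names(gdx)), sort(c(a, "W")))
  }
})

test_that("partial editing splits into dominant and recessive edit classes", {
  s <- make_strategy("pdne1", u = 0.6, frac_recessive = 0.25)
  gd <- gamete_distribution("G/W|F", s$arch, s$params)
  expect_equal(gd[["G"]], 0.5)
  expect_equal(gd[["W"]], 0.5 * 0.4)
  expect_equal(gd[["E_dom"]], 0.5 * 0.6 * 0.75)
  expect_equal(gd[["E_rec"]], 0.5 * 0.6 * 0.25)
})

test_that("gamete distributions reduce to Mendelian segregation with recombination", {
  # brute-force oracle over all two-locus haplotype pairs, editing silenced
  s <- make_strategy("pdne2", u = 0, mu_lof = 0)
  haps <- as.matrix(expand.grid(A = c("W", "G"), B = c("Wb", "Eb"),
                                stringsAsFactors = FALSE))
  for (r in c(0, 0.1, 0.3, 0.5)) {
    params <- override_params(s$params, list(recomb_r = r))
    for (i in seq_len(nrow(haps))) for (j in seq_len(nrow(haps))) {
      g <- geno_key(haps[i, ], haps[j, ], "F")
      gd <- gamete_distribution(g, s$arch, params)
      oracle <- mendelian_two_locus_oracle(haps[i, ], haps[j, ], r)
      expect_equal(gd[order(names(gd))], oracle[order(names(oracle))],
                   tolerance = 1e-12)
    }
  }
})

test_that("distributions are normalized and segregation conserves allele frequency", {
  # property over every genotype in several strategies' closures, with
  # editing/homing/shredding/mutation silenced allele counts must be
  # conserved; with them active distributions must still normalize
  set.seed(42)
  strategies <- list(
    make_strategy("pdne1", u = 0.7, frac_recessive = 0.2, mu_lof = 0.02),
    make_strategy("pdne2", u = 0.5),
    make_strategy("xs", shred_rate = 0.8),
    make_strategy("pdne1", booster = "homing", sex_limited_edit = "female_only"),
    make_strategy("fsridl_drive", homing_rate = 0.6))
  for (st in strategies) {
    eng <- drivebalance:::compile_engine(st)
    for (g in eng$genos) {
      gd <- gamete_distribution(g, st$arch, st$params)
      expect_equal(sum(gd), 1, tolerance = 1e-12)
      expect_true(all(gd >= 0 & gd <= 1))
    }
    # neutral parameters: conservation of allele frequency
    neutral <- override_params(st$params,
                               list(u = 0, mu_lof = 0, homing_rate = 0,
                                    shred_rate = 0))
    for (g in sample(eng$genos, min(6, length(eng$genos)))) {
      gd <- gamete_distribution(g, st$arch, neutral)
      expect_equal(sum(gd), 1, tolerance = 1e-12)
      pg <- geno_parse(g)
      for (locus in seq_len(st$arch$n_loci)) {
        a <- pg$h1[locus]
        parent_freq <- mean(c(pg$h1[locus], pg$h2[locus]) == a)
        expect_equal(gamete_allele_freq(gd, locus, a), parent_freq,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("loss-of-function mutation degrades construct components independently", {
  mu <- 0.01
  s <- make_strategy("pdne1", u = 0, mu_lof = mu)
  gd <- gamete_distribution("G/G|M", s$arch, s$params)
  expect_equal(gd[["G"]], (1 - mu)^2)
  expect_equal(gd[["G_dCas9"]], mu * (1 - mu))
  expect_equal(gd[["G_dgRNA"]], mu * (1 - mu))
  expect_equal(gd[["G_dBoth"]], mu^2)
  # single-component derivatives can only lose their remaining component
  gd2 <- gamete_distribution("G_dCas9/G_dCas9|M", s$arch, s$params)
  expect_equal(gd2[["G_dCas9"]], 1 - mu)
  expect_equal(gd2[["G_dBoth"]], mu)
})

test_that("X-shredding biases male gametes toward Y and renormalizes", {
  s <- make_strategy("xs", shred_rate = 0.8)
  gd <- gamete_distribution(geno_key(c("S", "X"), c("Ws", "Y"), "M"),
                            s$arch, s$params)
  expect_equal(sum(gd), 1, tolerance = 1e-12)
  haps <- strsplit(names(gd), ":", fixed = TRUE)
  y_share <- sum(gd[vapply(haps, function(h) h[2] == "Y", logical(1))])
  expect_equal(y_share, 0.5 / (0.5 + 0.5 * 0.2), tolerance = 1e-12)
  # females never shred
  gf <- gamete_distribution(geno_key(c("S", "X"), c("S", "X"), "F"),
                            s$arch, s$params)
  expect_equal(sum(gf), 1, tolerance = 1e-12)
  expect_equal(unname(gf), 1)
})

test_that("the homing booster converts wild-type alleles to the construct", {
  s <- make_strategy("pdne1", booster = "homing")
  g <- geno_key(c("G", "H_homing"), c("W", "Wc"), "M")
  gd <- gamete_distribution(g, s$arch, s$params)
  # homing_rate = 1: every gamete carries the construct at the first locus
  haps <- strsplit(names(gd), ":", fixed = TRUE)
  expect_true(all(vapply(haps, function(h) h[1] == "G", logical(1))))
  # without the booster allele, heterozygotes edit instead of homing
  g2 <- geno_key(c("G", "Wc"), c("W", "Wc"), "M")
  gd2 <- gamete_distribution(g2, s$arch, s$params)
  expect_true(any(vapply(strsplit(names(gd2), ":", fixed = TRUE),
                         function(h) h[1] == "E_dom", logical(1))))
})

test_that("offspring distributions multiply gamete tables and flag sterility", {
  s <- make_strategy("pdne1")
  wt <- "W/W|F"
  off <- offspring_distribution(wt, "G/W|M", s$arch, s$params)
  expect_equal(sum(off), 1, tolerance = 1e-12)
  expect_equal(off[["G/W|F"]], 0.25)
  expect_equal(off[["E_dom/W|M"]], 0.25)
  # wild x wild is the identity (up to sex)
  off_wt <- offspring_distribution(wt, "W/W|M", s$arch, s$params)
  expect_equal(off_wt[order(names(off_wt))],
               c("W/W|F" = 0.5, "W/W|M" = 0.5))
  # a sterile parent yields an empty, flagged distribution
  sf <- make_strategy("pdne1", timing = "fertility")
  empty <- offspring_distribution("E_dom/W|F", "W/W|M", sf$arch, sf$params)
  expect_length(empty, 0)
  expect_true(attr(empty, "sterile"))
})

test_that("unknown allele symbols are configuration errors", {
  s <- make_strategy("pdne1")
  expect_error(gamete_distribution("Z/W|M", s$arch, s$params),
               "unknown allele")
  expect_error(viability("G/Q|F", s$arch, s$params), "unknown allele")
})
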