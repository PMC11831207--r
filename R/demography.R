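# Discrete-generation, sex-structured demography --------------------------
#
# Two life stages (juveniles, adults), non-overlapping generations, juvenile
# density-dependent mortality.  Counts are normalized so that the all-wild-
# type equilibrium has 1 adult female and 1 adult male.  One generation:
#
#   1. released males are injected into the adult male pool;
#   2. every fertile female mates once, the father drawn in proportion to
#      fertile-male counts;
#   3. each female produces 2*Rm juveniles, distributed over offspring
#      genotypes;
#   4. early-acting genetic deaths;
#   5. uniform density-dependent survival sigma = 1 / (1 + (Rm - 1) *
#      (J/J0)^dd_exponent), with J the post-early juvenile total and
#      J0 = 2*Rm its wild-type equilibrium value (Beverton-Holt when
#      dd_exponent = 1);
#   6. late-acting genetic deaths;
#   7. survivors are the next adult generation.

#' Life-cycle (demographic) parameters
#'
#' @param Rm Intrinsic rate of increase: per-generation low-density growth
#'   factor of the population (must exceed 1).
#' @param dd_exponent Shape of juvenile density dependence; 1 (the default)
#'   is the Beverton-Holt form.
#' @return An object of class `life_cycle`.
#' @examples life_cycle(Rm = 6)
#' @export
life_cycle <- function(Rm, dd_exponent = 1) {
  if (!is.numeric(Rm) || length(Rm) != 1L || is.na(Rm) || Rm <= 1)
    stop("Rm must be a single number > 1", call. = FALSE)
  if (!is.numeric(dd_exponent) || dd_exponent <= 0)
    stop("dd_exponent must be positive", call. = FALSE)
  structure(list(Rm = Rm, dd_exponent = dd_exponent, F0 = 1, M0 = 1),
            class = "life_cycle")
}

#' Release schedule
#'
#' @param rho Number of released males per release, as a proportion of the
#'   original (pre-release equilibrium) male population.
#' @param cadence `"every"` (each generation) or `"single"`.
#' @param start,stop First and last generation of releases (1-based;
#'   `stop = Inf` means indefinitely).
#' @param genotype Released genotype key; defaults to the strategy's
#'   canonical release genotype.
#' @return An object of class `release_schedule`.
#' @export
release_schedule <- function(rho, cadence = c("every", "single"),
                             start = 1L, stop = Inf, genotype = NULL) {
  cadence <- match.arg(cadence)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
    stop("rho must be a single number >= 0", call. = FALSE)
  if (cadence == "single") stop <- start
  structure(list(rho = rho, cadence = cadence, start = start, stop = stop,
                 genotype = genotype),
            class = "release_schedule")
}

release_active <- function(release, t) {
  release$rho > 0 && t >= release$start && t <= release$stop
}

#' All-wild-type equilibrium state
#'
#' @param strategy A `gd_strategy` (defines the architecture).
#' @param lc A [life_cycle()].
#' @return Named count vector over genotype keys: one adult female and one
#'   adult male, all wild type.  [step_population()] maps it to itself.
#' @export
equilibrium_state <- function(strategy, lc = life_cycle(6)) {
  wt <- wild_genotypes(strategy$arch)
  stats::setNames(c(1, 1), unname(wt))
}

# Engine compilation -------------------------------------------------------
# Enumerates the closure of genotypes reachable from the seed genotypes
# (wild types + released genotype) under mating, and precomputes the
# offspring matrix OFF[(father, mother) pair, offspring genotype], viability
# vectors and haplotype/allele projections.

compile_engine <- function(strategy, extra_genotypes = character(0)) {
  arch <- strategy$arch
  params <- strategy$params
  seeds <- unique(c(unname(wild_genotypes(arch)), strategy$release_genotype,
                    extra_genotypes))

  off_memo <- new.env(parent = emptyenv())
  off_of <- function(f, m) {
    k <- paste0(f, "%", m)
    v <- off_memo[[k]]
    if (is.null(v)) {
      v <- offspring_distribution(f, m, arch, params)
      off_memo[[k]] <- v
    }
    v
  }

  genos <- seeds
  done_pairs <- character(0)
  repeat {
    sexes <- substr(genos, nchar(genos), nchar(genos))
    fs <- genos[sexes == "F"]
    ms <- genos[sexes == "M"]
    pairs <- as.vector(outer(fs, ms, paste, sep = "%"))
    new_pairs <- setdiff(pairs, done_pairs)
    if (!length(new_pairs)) break
    added <- character(0)
    for (p in new_pairs) {
      fm <- strsplit(p, "%", fixed = TRUE)[[1]]
      off <- off_of(fm[1], fm[2])
      added <- c(added, names(off))
    }
    done_pairs <- c(done_pairs, new_pairs)
    genos <- unique(c(genos, added))
  }

  genos <- sort(genos)
  nG <- length(genos)
  sex <- substr(genos, nchar(genos), nchar(genos))
  viab <- lapply(genos, viability, arch = arch, params = params)
  early <- vapply(viab, `[[`, numeric(1), "early_survival")
  late <- vapply(viab, `[[`, numeric(1), "late_survival")
  fert <- vapply(viab, `[[`, numeric(1), "fertility")

  f_idx <- which(sex == "F")
  m_idx <- which(sex == "M")
  nF <- length(f_idx)
  nM <- length(m_idx)
  OFF <- matrix(0, nF * nM, nG, dimnames = list(NULL, genos))
  for (mi in seq_len(nM)) for (fi in seq_len(nF)) {
    off <- off_of(genos[f_idx[fi]], genos[m_idx[mi]])
    if (length(off)) OFF[(mi - 1L) * nF + fi, names(off)] <- off
  }

  # haplotype / allele bookkeeping for frequency reporting
  parsed <- lapply(genos, geno_parse)
  haps <- sort(unique(unlist(lapply(parsed, function(g)
    c(hap_key(g$h1), hap_key(g$h2))))))
  hap_of_geno <- t(vapply(parsed, function(g)
    c(match(hap_key(g$h1), haps), match(hap_key(g$h2), haps)), integer(2)))
  hap_alleles <- do.call(rbind, lapply(haps, hap_parse))
  allele_cols <- list()
  for (i in seq_len(arch$n_loci)) {
    role <- arch$loci[[i]]$role
    for (a in arch$loci[[i]]$alleles) {
      allele_cols[[paste0(role, ".", a)]] <-
        as.numeric(hap_alleles[, i] == a)
    }
  }
  A <- do.call(cbind, allele_cols)   # nHap x nAlleleCols

  list(strategy = strategy, genos = genos, sex = sex,
       early = early, late = late, fert = fert,
       f_idx = f_idx, m_idx = m_idx, OFF = OFF,
       haps = haps, hap_of_geno = hap_of_geno, A = A)
}

counts_to_vec <- function(counts, engine) {
  v <- stats::setNames(numeric(length(engine$genos)), engine$genos)
  if (length(counts)) {
    unknown <- setdiff(names(counts), engine$genos)
    if (length(unknown))
      stop("genotype(s) outside the engine's closure: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    v[names(counts)] <- v[names(counts)] + counts
  }
  v
}

# One generation.  `counts` is the adult count vector (engine order);
# `release_counts` (same length) is added to the male pool before mating.
# Returns list(counts, J, load).
engine_step <- function(counts, engine, lc, release_counts = NULL) {
  if (any(counts < -1e-12))
    stop("internal error: negative adult counts", call. = FALSE)
  Rm <- lc$Rm
  m <- counts
  m[engine$f_idx] <- 0
  if (!is.null(release_counts)) m <- m + release_counts
  wm <- m * engine$fert
  fe <- counts[engine$f_idx] * engine$fert[engine$f_idx]
  f_all <- sum(counts[engine$f_idx])
  S <- sum(wm)
  if (S <= 0 || sum(fe) <= 0) {
    zero <- counts * 0
    return(list(counts = zero, J = 0, load = NA_real_))
  }
  pairw <- as.vector(outer(fe, wm[engine$m_idx] / S))
  juv <- 2 * Rm * as.vector(pairw %*% engine$OFF)
  juv_early <- juv * engine$early
  J <- sum(juv_early)
  load <- if (f_all > 0)
    1 - sum(juv_early * engine$late) / (2 * Rm * f_all) else NA_real_
  J0 <- 2 * Rm               # wild-type equilibrium juvenile total (F0 = 1)
  sigma <- 1 / (1 + (Rm - 1) * (J / J0)^lc$dd_exponent)
  nxt <- juv_early * sigma * engine$late
  list(counts = stats::setNames(nxt, engine$genos), J = J, load = load)
}

#' Advance a population state by one generation
#'
#' User-facing wrapper around the compiled engine: takes and returns named
#' genotype-count vectors.
#'
#' @param counts Named adult count vector (genotype keys).
#' @param strategy A `gd_strategy`.
#' @param lc A [life_cycle()].
#' @param release Optional [release_schedule()]; its `rho` males are
#'   injected before mating (cadence/start are ignored here).
#' @return Named adult count vector for the next generation.
#' @export
step_population <- function(counts, strategy, lc, release = NULL) {
  engine <- compile_engine(strategy, extra_genotypes = names(counts))
  v <- counts_to_vec(counts, engine)
  rel <- NULL
  if (!is.null(release) && release$rho > 0) {
    gt <- release$genotype %||% strategy$release_genotype
    rel <- counts_to_vec(stats::setNames(release$rho * lc$M0, gt), engine)
  }
  engine_step(v, engine, lc, rel)$counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a release program
#'
#' Runs the deterministic recursion for `horizon` generations, recording
#' per-generation adult female and male counts (relative to the wild-type
#' equilibrium), allele and haplotype frequencies (adults, sexes pooled) and
#' the realized genetic load (the proportional reduction, by genetic deaths
#' and sterility, of offspring production relative to a wild-type population
#' of the same adult female count; reported for the reproduction producing
#' each generation).
#'
#' Generation 0 is the pre-release state; releases occur in generations
#' `release$start` .. `release$stop`, so the row at generation t reflects t
#' rounds of reproduction (and any releases up to t).
#'
#' @param strategy A `gd_strategy` from [make_strategy()].
#' @param lc A [life_cycle()].
#' @param release A [release_schedule()].
#' @param horizon Number of generations to simulate (>= 1 unless 0 for the
#'   initial record only).
#' @param init Optional named genotype-count vector replacing the wild-type
#'   equilibrium as initial adult state.
#' @return An object of class `gd_sim`: list with `series` (data frame:
#'   generation, females_rel, males_rel, load), `allele_freq` and `hap_freq`
#'   matrices (one row per generation), plus the inputs.
#' @examples
#' s <- make_strategy("pdne1")
#' sim <- simulate_release(s, life_cycle(6), release_schedule(0.1), horizon = 10)
#' sim$series$females_rel
#' @export
simulate_release <- function(strategy, lc = life_cycle(6),
                             release = release_schedule(0.1),
                             horizon = 36L, init = NULL) {
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  engine <- compile_engine(strategy,
                           extra_genotypes = c(names(init) %||% character(0),
                                               release$genotype %||% character(0)))
  counts <- if (is.null(init)) counts_to_vec(equilibrium_state(strategy, lc), engine)
            else counts_to_vec(init, engine)
  rel_vec <- counts_to_vec(
    stats::setNames(1, release$genotype %||% strategy$release_genotype),
    engine)

  nT <- horizon + 1L
  females <- males <- load <- numeric(nT)
  hap_freq <- matrix(NA_real_, nT, length(engine$haps),
                     dimnames = list(NULL, engine$haps))
  record <- function(t, counts, ld) {
    females[t + 1L] <<- sum(counts[engine$f_idx])
    males[t + 1L] <<- sum(counts[engine$m_idx])
    load[t + 1L] <<- ld
    hc <- numeric(length(engine$haps))
    for (k in which(counts > 0)) {
      hc[engine$hap_of_geno[k, 1]] <- hc[engine$hap_of_geno[k, 1]] + counts[k]
      hc[engine$hap_of_geno[k, 2]] <- hc[engine$hap_of_geno[k, 2]] + counts[k]
    }
    tot <- sum(hc)
    hap_freq[t + 1L, ] <<- if (tot > 0) hc / tot else NA_real_
  }

  record(0L, counts, NA_real_)
  for (t in seq_len(horizon)) {
    rel <- if (release_active(release, t)) rel_vec * (release$rho * lc$M0)
           else NULL
    st <- engine_step(counts, engine, lc, rel)
    counts <- st$counts
    record(t, counts, st$load)
  }

  allele_freq <- hap_freq %*% engine$A
  series <- data.frame(generation = 0:horizon, females_rel = females,
                       males_rel = males, load = load)
  structure(list(series = series, allele_freq = allele_freq,
                 hap_freq = hap_freq, strategy = strategy, lc = lc,
                 release = release, horizon = horizon,
                 final_counts = counts, engine_genos = engine$genos),
            class = "gd_sim")
}

# First generation (>= 1) at which the female count reaches the suppression
# threshold, or NA.
first_passage <- function(sim, target) {
  thr <- (1 - target) * sim$lc$F0 + 1e-12
  f <- sim$series$females_rel
  hit <- which(f[-1] <= thr)
  if (length(hit)) hit[1] else NA_integer_
}
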