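# Headline experiments -----------------------------------------------------

#' Minimal release rate achieving a suppression goal
#'
#' Bisection on the per-generation release proportion `rho` for the smallest
#' release that suppresses the adult female population by `target` within
#' `horizon` generations.  Success is first passage: the female count
#' reaches `(1 - target) * F0` at *some* generation `<= horizon`
#' (`metric = "at_horizon"` instead requires it at generation `horizon`).
#' Suppression is monotone in `rho` for every modeled strategy, which the
#' bracketing step relies on.
#'
#' @param strategy A `gd_strategy`.
#' @param lc A [life_cycle()].
#' @param target Suppression level in (0, 1), e.g. 0.95.
#' @param horizon Generations allowed to reach the goal.
#' @param rho_max Upper bracket for the search; a target not attainable at
#'   `rho_max` is reported as unattainable, not an error.
#' @param tol Absolute tolerance on `rho`.
#' @param metric `"first_passage"` or `"at_horizon"`.
#' @param cadence Release cadence passed to [release_schedule()].
#' @return An object of class `gd_search`: list with `strategy_name`, `Rm`,
#'   `target`, `horizon`, `rho_star` (NA if unattainable), `attainable`,
#'   `achieved_generation`, `tol`, `metric`.
#' @examples
#' \donttest{
#' min_release_rate(make_strategy("pdne1"), life_cycle(20),
#'                  target = 0.95, horizon = 36)
#' }
#' @export
min_release_rate <- function(strategy, lc, target = 0.95, horizon = 36L,
                             rho_max = 20, tol = 1e-4,
                             metric = c("first_passage", "at_horizon"),
                             cadence = "every") {
  metric <- match.arg(metric)
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)",
                                       call. = FALSE)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  engine <- compile_engine(strategy)
  thr <- (1 - target) * lc$F0 + 1e-12

  achieved <- function(rho) {
    sim <- run_compiled(engine, lc, rho, horizon, cadence)
    f <- sim$females
    if (metric == "first_passage") {
      hit <- which(f <= thr)
      if (length(hit)) hit[1] else NA_integer_
    } else {
      if (f[horizon] <= thr) horizon else NA_integer_
    }
  }

  res <- list(strategy_name = strategy$name, Rm = lc$Rm, target = target,
              horizon = horizon, rho_star = NA_real_, attainable = FALSE,
              achieved_generation = NA_integer_, tol = tol, metric = metric)
  class(res) <- "gd_search"
  hi_gen <- achieved(rho_max)
  if (is.na(hi_gen)) return(res)

  lo <- 0; hi <- rho_max
  iter <- 0L
  while (hi - lo > tol && iter < 60L) {
    mid <- (lo + hi) / 2
    if (!is.na(achieved(mid))) hi <- mid else lo <- mid
    iter <- iter + 1L
  }
  res$rho_star <- hi
  res$attainable <- TRUE
  res$achieved_generation <- achieved(hi)
  res
}

# Lean inner simulation used by the searches: female-count trajectory only.
run_compiled <- function(engine, lc, rho, horizon, cadence = "every") {
  counts <- stats::setNames(numeric(length(engine$genos)), engine$genos)
  wt <- wild_genotypes(engine$strategy$arch)
  counts[unname(wt)] <- 1
  rel <- counts * 0
  rel[engine$strategy$release_genotype] <- rho * lc$M0
  females <- numeric(horizon)
  for (t in seq_len(horizon)) {
    r <- if (rho > 0 && (cadence == "every" || t == 1L)) rel else NULL
    counts <- engine_step(counts, engine, lc, r)$counts
    females[t] <- sum(counts[engine$f_idx])
  }
  list(females = females)
}

#' @export
print.gd_search <- function(x, ...) {
  cat("<gd_search> ", x$strategy_name,
      sprintf(": Rm = %g, %g%% suppression within %d generations\n",
              x$Rm, 100 * x$target, x$horizon), sep = "")
  if (x$attainable)
    cat(sprintf("  minimal release proportion rho* = %.5f (first reached at generation %d)\n",
                x$rho_star, x$achieved_generation))
  else
    cat("  unattainable within the release bracket\n")
  invisible(x)
}

#' Fold difference in release-rate requirements
#'
#' Ratio of the minimal release rates of two strategies under identical
#' demography and suppression goal (e.g. SIT over PDNE: how many times more
#' males the sterile-male program must release).
#'
#' @param a,b `gd_search` results for the same `Rm`, `target`, `horizon`.
#' @return `a$rho_star / b$rho_star`.
#' @export
fold_efficiency <- function(a, b) {
  for (f in c("Rm", "target", "horizon"))
    if (!isTRUE(all.equal(a[[f]], b[[f]])))
      stop("search results differ in `", f, "`", call. = FALSE)
  if (!a$attainable || !b$attainable)
    stop("fold efficiency undefined for unattainable targets", call. = FALSE)
  if (b$rho_star <= 0)
    stop("fold efficiency undefined: reference release rate is 0",
         call. = FALSE)
  a$rho_star / b$rho_star
}

#' Sweep one genetic parameter against the release-rate requirement
#'
#' Re-runs [min_release_rate()] over a grid of values of a single
#' [genetic_params()] field, all other parameters held at the strategy's
#' values.  Unattainable grid points are flagged rather than dropped:
#' beyond a robustness threshold the strategy fails outright.
#'
#' @inheritParams min_release_rate
#' @param param Name of the swept `genetic_params` field (e.g. `"u"`,
#'   `"s_edit"`, `"h_construct"`, `"mu_lof"`).
#' @param grid Numeric vector of values.
#' @return Data frame with one row per grid point: `param`, `value`,
#'   `rho_star`, `attainable`, `achieved_generation`.
#' @export
parameter_sweep <- function(strategy, param, grid, lc, target = 0.95,
                            horizon = 36L, rho_max = 20, tol = 1e-4) {
  if (!param %in% names(unclass(strategy$params)))
    stop("`", param, "` is not a genetic parameter", call. = FALSE)
  rows <- lapply(grid, function(v) {
    st <- strategy
    st$params <- override_params(st$params, stats::setNames(list(v), param))
    r <- min_release_rate(st, lc, target = target, horizon = horizon,
                          rho_max = rho_max, tol = tol)
    data.frame(param = param, value = v, rho_star = r$rho_star,
               attainable = r$attainable,
               achieved_generation = r$achieved_generation)
  })
  out <- do.call(rbind, rows)
  attr(out, "target") <- target
  attr(out, "horizon") <- horizon
  attr(out, "Rm") <- lc$Rm
  out
}

#' Construct-booster correlation from haplotype frequencies
#'
#' The correlation between the construct-presence and booster-presence
#' indicators over haplotypes:
#' `(p_GB - p_G * p_B) / sqrt(p_G (1 - p_G) p_B (1 - p_B))`, where `p_GB`
#' is the frequency of haplotypes carrying both elements.  Applied to a
#' `gd_sim` of a boosted PDNE it returns the per-generation trajectory;
#' generations where either element is absent or fixed are `NA` (the
#' correlation is undefined there).
#'
#' @param sim A `gd_sim` from a strategy with a booster locus, or a numeric
#'   vector `c(p_GB, p_G, p_B)`.
#' @return Numeric vector of correlations in `[-1, 1]`.
#' @export
linkage_correlation <- function(sim) {
  if (is.numeric(sim)) {
    if (length(sim) != 3L)
      stop("numeric input must be c(p_GB, p_G, p_B)", call. = FALSE)
    return(ld_correlation(sim[1], sim[2], sim[3]))
  }
  if (!inherits(sim, "gd_sim")) stop("need a gd_sim or c(p_GB, p_G, p_B)",
                                     call. = FALSE)
  arch <- sim$strategy$arch
  li_c <- arch_locus(arch, "pdne")
  if (is.na(li_c)) li_c <- arch_locus(arch, "pdne_construct")
  li_b <- arch_locus(arch, "homing_booster")
  if (is.na(li_b)) li_b <- arch_locus(arch, "cnr_booster")
  if (is.na(li_c) || is.na(li_b))
    stop("simulation has no construct + booster loci", call. = FALSE)
  haps <- do.call(rbind, lapply(colnames(sim$hap_freq), hap_parse))
  has_g <- haps[, li_c] %in% G_CLASS
  has_b <- haps[, li_b] %in% c("H_homing", "B_cnr")
  p_g <- rowSums(sim$hap_freq[, has_g, drop = FALSE])
  p_b <- rowSums(sim$hap_freq[, has_b, drop = FALSE])
  p_gb <- rowSums(sim$hap_freq[, has_g & has_b, drop = FALSE])
  out <- rep(NA_real_, length(p_g))
  ok <- p_g > 0 & p_g < 1 & p_b > 0 & p_b < 1
  out[ok] <- (p_gb[ok] - p_g[ok] * p_b[ok]) /
    sqrt(p_g[ok] * (1 - p_g[ok]) * p_b[ok] * (1 - p_b[ok]))
  out
}

ld_correlation <- function(p_gb, p_g, p_b) {
  if (p_g <= 0 || p_g >= 1 || p_b <= 0 || p_b >= 1)
    stop("correlation undefined: an element is absent or fixed",
         call. = FALSE)
  (p_gb - p_g * p_b) / sqrt(p_g * (1 - p_g) * p_b * (1 - p_b))
}

#' Loss-of-function derivative scan
#'
#' Simulates a construct release with per-component loss-of-function
#' mutation (`mu_lof > 0`) and tracks the frequencies of the intact
#' construct and of each deletion derivative (Cas9-dead, gRNA-dead, both
#' dead).  None of the derivatives can drive: the scan flags whether any
#' derivative ever exceeds the original construct's release frequency (the
#' construct allele frequency in the population immediately after the first
#' injection).
#'
#' @inheritParams simulate_release
#' @return List with `sim` (the `gd_sim`), `trajectories` (data frame of
#'   per-generation allele frequencies for `G`, `G_dCas9`, `G_dgRNA`,
#'   `G_dBoth`), `release_frequency`, `max_derivative_frequency` and
#'   `contained` (logical).
#' @export
lof_derivative_scan <- function(strategy, lc = life_cycle(6),
                                release = release_schedule(0.1),
                                horizon = 50L) {
  if (strategy$params$mu_lof <= 0)
    stop("lof_derivative_scan requires mu_lof > 0", call. = FALSE)
  sim <- simulate_release(strategy, lc, release, horizon)
  role <- if (!is.na(arch_locus(strategy$arch, "pdne"))) "pdne"
          else "pdne_construct"
  cols <- paste0(role, ".", c("G", "G_dCas9", "G_dgRNA", "G_dBoth"))
  traj <- as.data.frame(sim$allele_freq[, cols])
  names(traj) <- c("G", "G_dCas9", "G_dgRNA", "G_dBoth")
  traj <- cbind(generation = sim$series$generation, traj)

  # construct frequency immediately after the first injection
  g <- geno_parse(release$genotype %||% strategy$release_genotype)
  li <- arch_locus(strategy$arch, role)
  copies <- sum(c(g$h1[li], g$h2[li]) == "G")
  n_rel <- release$rho * lc$M0
  ploidy <- 2
  release_freq <- (copies * n_rel) /
    (ploidy * (lc$F0 + lc$M0 + n_rel))

  deriv_max <- max(traj[, c("G_dCas9", "G_dgRNA", "G_dBoth")])
  list(sim = sim, trajectories = traj, release_frequency = release_freq,
       max_derivative_frequency = deriv_max,
       contained = deriv_max <= release_freq + 1e-12)
}
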