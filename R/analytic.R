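# Closed-form single-locus model ------------------------------------------
#
# Infinite, panmictic, single-sex population; one autosomal locus with a
# wild-type allele, the construct (a germline editor protected in cis) and
# the edits it creates.  Edits are embryonic lethals, so frequencies are
# censused at the hatchling stage, after embryonic deaths; the construct's
# recessive lethality acts later, between census and reproduction.  Under
# idealized parameters the construct's preferential transmission exactly
# cancels selection against its recessive lethality, making it neutral
# while still imposing a reproductive load on the population.

#' Fitness components of the construct at frequency q
#'
#' Relative fitness of the construct due to its recessive lethality
#' (`w_rec = 1 - q`), due to drive from the protected editor
#' (`w_dom = 1/(1 - q)`), and their product (`w_total = 1`): the
#' drive-selection balance.
#'
#' @param q Construct frequency at the hatchling census, in `[0, 1)`.
#' @return List with `w_rec`, `w_dom`, `w_total`.
#' @examples fitness_components(0.5)
#' @export
fitness_components <- function(q) {
  check_freq(q, upper_open = TRUE)
  w_rec <- 1 - q
  w_dom <- 1 / (1 - q)
  list(w_rec = w_rec, w_dom = w_dom, w_total = w_rec * w_dom)
}

#' Reproductive load imposed by the construct
#'
#' `L = 2q / (1 + q)`: the proportional reduction in reproductive output,
#' relative to an all-wild-type population, over one generation.  It arises
#' half from recessive lethality of construct homozygotes and half from the
#' dominant lethal edits created in heterozygotes' unprotected gametes.
#'
#' @param q Construct frequency in `[0, 1]` (vectorized).
#' @return Load in `[0, 1]`.
#' @examples reproductive_load(c(0, 1/3, 1))
#' @export
reproductive_load <- function(q) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  2 * q / (1 + q)
}

#' Fitness from a one-generation frequency change
#'
#' The relative fitness implied by a change in construct frequency across
#' one generation, censused at hatching: the odds ratio
#' `[q'/(1-q')] / [q/(1-q)]`.
#'
#' @param q_t,q_t1 Frequencies at successive hatchling censuses, in (0, 1).
#' @return Fitness `w`.
#' @examples fitness_from_frequencies(0.25, 0.4)
#' @export
fitness_from_frequencies <- function(q_t, q_t1) {
  check_freq(q_t, lower_open = TRUE, upper_open = TRUE)
  check_freq(q_t1, lower_open = TRUE, upper_open = TRUE)
  (q_t1 / (1 - q_t1)) / (q_t / (1 - q_t))
}

#' Drive-prevention condition
#'
#' With fully dominant, fully penetrant lethal edits, the construct cannot
#' drive (its fitness stays below one at all frequencies) as long as
#' `(s - h*s) / (1 - h*s) >= u`, where `s` is the homozygous construct
#' cost, `h*s` its heterozygous cost and `u` the editing rate.  With
#' `s = 1` the condition holds for any `u`.
#'
#' @param s Homozygous fitness cost of the construct, in `[0, 1]`.
#' @param h Dominance coefficient of the construct, in `[0, 1]`.
#' @param u Editing rate, in `[0, 1]`.
#' @return Logical (vectorized).
#' @examples no_drive_condition(s = 0.5, h = 0.2, u = 0.4)
#' @export
no_drive_condition <- function(s, h, u) {
  if (any(s < 0 | s > 1 | h < 0 | h > 1 | u < 0 | u > 1))
    stop("s, h, u must lie in [0, 1]", call. = FALSE)
  hs <- h * s
  if (any(hs >= 1))
    stop("condition undefined when h*s = 1 (no surviving heterozygotes)",
         call. = FALSE)
  (s - hs) / (1 - hs) >= u
}

check_freq <- function(q, lower_open = FALSE, upper_open = FALSE) {
  lo_bad <- if (lower_open) q <= 0 else q < 0
  hi_bad <- if (upper_open) q >= 1 else q > 1
  if (any(lo_bad | hi_bad))
    stop("frequency outside ", if (lower_open) "(" else "[", "0, 1",
         if (upper_open) ")" else "]", call. = FALSE)
  invisible(q)
}

# Internal fixed enumeration for the analytic recursion: alleles W, G,
# E_dom, E_rec; 10 unordered genotypes.  Gamete frequencies are computed in
# closed form per genotype (editing at rate u in carriers of the functional
# editor; a fraction frac_recessive of edits is recessive); viability comes
# from the shared viability() rules on the single-locus architecture.
ANALYTIC_ALLELES <- c("W", "G", "E_dom", "E_rec")

analytic_compile <- function(params) {
  validate_genetic_params(params)
  if (params$mu_lof > 0)
    stop("the analytic model does not include loss-of-function mutation",
         call. = FALSE)
  arch <- gd_architecture("pdne")
  al <- ANALYTIC_ALLELES
  pairs <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  nGeno <- nrow(pairs)

  GM <- matrix(0, nGeno, 4, dimnames = list(NULL, al))
  u <- params$u; fr <- params$frac_recessive
  for (k in seq_len(nGeno)) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    editor <- 2L %in% c(a, b)      # functional editor allele G present
    for (i in c(a, b)) {
      if (i == 1L && editor) {     # wild-type target allele, edited at u
        GM[k, "W"] <- GM[k, "W"] + 0.5 * (1 - u)
        GM[k, "E_dom"] <- GM[k, "E_dom"] + 0.5 * u * (1 - fr)
        GM[k, "E_rec"] <- GM[k, "E_rec"] + 0.5 * u * fr
      } else {
        GM[k, i] <- GM[k, i] + 0.5
      }
    }
  }

  keys <- vapply(seq_len(nGeno), function(k)
    geno_key(al[pairs[k, 1]], al[pairs[k, 2]], "F"), character(1))
  viab <- lapply(keys, viability, arch = arch, params = params)
  zyg_index <- matrix(0L, 4, 4)
  for (k in seq_len(nGeno)) {
    zyg_index[pairs[k, 1], pairs[k, 2]] <- k
    zyg_index[pairs[k, 2], pairs[k, 1]] <- k
  }
  list(pairs = pairs, GM = GM, keys = keys,
       early = vapply(viab, `[[`, numeric(1), "early_survival"),
       late = vapply(viab, `[[`, numeric(1), "late_survival"),
       fert = vapply(viab, `[[`, numeric(1), "fertility"),
       zyg_index = zyg_index,
       g_count = (pairs[, 1] == 2L) + (pairs[, 2] == 2L))
}

analytic_hw_state <- function(q, eng) {
  x <- numeric(nrow(eng$pairs))
  x[eng$zyg_index[1, 1]] <- (1 - q)^2
  x[eng$zyg_index[1, 2]] <- 2 * q * (1 - q)
  x[eng$zyg_index[2, 2]] <- q^2
  x
}

analytic_iterate <- function(x, eng) {
  w <- x * eng$late * eng$fert
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  g <- as.vector((w / tot) %*% eng$GM)
  z <- outer(g, g)
  xz <- numeric(length(x))
  idx <- eng$zyg_index
  for (i in 1:4) for (j in 1:4) xz[idx[i, j]] <- xz[idx[i, j]] + z[i, j]
  xz <- xz * eng$early
  s <- sum(xz)
  if (s <= 0) return(NULL)
  xz / s
}

analytic_q <- function(x, eng, census, params) {
  if (census == "adult") {
    w <- x * eng$late * eng$fert
    x <- w / sum(w)
  }
  sum(x * eng$g_count) / 2
}

#' One generation of the single-locus recursion
#'
#' Starting from a hatchling population in Hardy-Weinberg proportions over
#' wild-type and construct alleles at construct frequency `q`, applies
#' post-census (construct) deaths, germline editing, random union of
#' gametes and embryonic (edit) deaths, and returns the construct frequency
#' at the next hatchling census.  Under idealized parameters this map is the
#' identity: the construct is selectively neutral.
#'
#' For the analytic model the edit cost is embryonic (`timing_edit =
#' "early"`) and the construct cost post-census; [analytic_params()] returns
#' the idealized parameterization with those timings.
#'
#' @param q Construct frequency in `[0, 1]`.
#' @param params A [genetic_params()] object (`mu_lof` must be 0).
#' @return The construct frequency at the next hatchling census.
#' @examples
#' analytic_step(0.3, analytic_params())   # = 0.3: drive-selection balance
#' @export
analytic_step <- function(q, params = analytic_params()) {
  check_freq(q)
  if (q == 0) return(0)
  eng <- analytic_compile(params)
  x <- analytic_iterate(analytic_hw_state(q, eng), eng)
  if (is.null(x)) return(NaN)
  q1 <- analytic_q(x, eng, "hatchling", params)
  min(max(q1, 0), 1)
}

#' Iterate the single-locus recursion
#'
#' @inheritParams analytic_step
#' @param q0 Initial construct frequency (hatchling census, Hardy-Weinberg).
#' @param generations Number of generations to iterate.
#' @param census `"hatchling"` (default) or `"adult"`: where the reported
#'   frequencies are measured.
#' @return Numeric vector of length `generations + 1` with the construct
#'   frequency trajectory (element 1 is generation 0).
#' @export
analytic_recursion <- function(q0, params = analytic_params(),
                               generations = 50L,
                               census = c("hatchling", "adult")) {
  census <- match.arg(census)
  check_freq(q0)
  eng <- analytic_compile(params)
  x <- analytic_hw_state(q0, eng)
  qs <- numeric(generations + 1L)
  qs[1] <- analytic_q(x, eng, census, params)
  for (t in seq_len(generations)) {
    x <- analytic_iterate(x, eng)
    if (is.null(x)) {
      qs[(t + 1L):(generations + 1L)] <- NaN
      break
    }
    qs[t + 1L] <- analytic_q(x, eng, census, params)
  }
  qs
}

#' Idealized parameters of the analytic model
#'
#' Editing always succeeds (`u = 1`), edits are fully dominant embryonic
#' lethals, the construct is a fully penetrant recessive lethal with no
#' heterozygous cost, acting after the hatchling census.
#'
#' @param ... Overrides of [genetic_params()] fields.
#' @return A `genetic_params` object.
#' @export
analytic_params <- function(...) {
  base <- genetic_params(u = 1, s_edit = 1, h_edit = 1, s_construct = 1,
                         h_construct = 0, timing_edit = "early",
                         timing_construct = "late")
  override_params(base, list(...))
}
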