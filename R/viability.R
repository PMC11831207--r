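# Stage-specific viability ------------------------------------------------

#' Stage-specific survival and fertility of a genotype
#'
#' Computes the genotype's early survival (deaths before density-dependent
#' juvenile mortality), late survival (after it) and fertility, by composing
#' the cost of every construct and edit it carries.  Costs are routed to the
#' stage named by `timing_edit` / `timing_construct`.
#'
#' Rules, per locus role:
#' * single-locus construct (`pdne`): construct-class and edited alleles all
#'   disrupt the haplosufficient host gene; when both copies are
#'   nonfunctional the recessive cost `s_construct` applies.  A single
#'   construct-class allele additionally pays the heterozygous construct
#'   cost `h_construct * s_construct`.  Each expressed dominant edit
#'   (`E_dom`) pays `h_edit * s_edit` (one copy) or `s_edit` (two); the
#'   construct haplotype can never carry an expressed edit (protection in
#'   cis), so `E_dom` is always expressed.
#' * two-locus design (`pdne_construct` + `hi_target`): the construct locus
#'   pays `s_construct` / `h_construct * s_construct` as above; death (cost
#'   `s_edit`) when functional haploinsufficient doses (wild-type copies
#'   plus recoded copies on construct alleles) fall below 2.
#' * `lethal` / `fsrd`: dominant lethal cassettes paying `h_edit * s_edit`
#'   heterozygous, `s_edit` homozygous, in both sexes or females only.
#' * sex pair: `X_edit` is a dominant female-specific edit (cost as above in
#'   females only).
#' * `hs2_target`: females with no functional copy (wild-type `Wd` or
#'   construct-borne rescue) die.
#'
#' `sex_limited_edit = "female_only"` exempts males from all edit-borne
#' costs (the construct's recessive and heterozygous costs stay bisex).
#'
#' @inheritParams gamete_distribution
#' @param genotype Genotype key or parsed genotype.
#' @return List with components `early_survival`, `late_survival`,
#'   `fertility`, each a probability.
#' @export
viability <- function(genotype, arch, params) {
  g <- if (is.character(genotype)) geno_parse(genotype) else genotype
  check_genotype(g, arch)
  validate_genetic_params(params)

  comp <- c(early = 1, late = 1, fertility = 1)
  stage <- function(timing) switch(timing, early = "early", late = "late",
                                   fertility = "fertility")
  pay <- function(mult, timing) {
    s <- stage(timing)
    comp[s] <<- comp[s] * mult
  }
  is_male <- identical(g$sex, "M")
  edits_exempt <- is_male && params$sex_limited_edit == "female_only"
  pair_at <- function(i) c(g$h1[i], g$h2[i])

  dominant_cost <- function(n, s, h) if (n >= 2L) 1 - s else 1 - h * s

  li_pdne <- arch_locus(arch, "pdne")
  li_pc <- arch_locus(arch, "pdne_construct")
  li_constr <- if (!is.na(li_pdne)) li_pdne else li_pc
  nG <- if (!is.na(li_constr)) sum(pair_at(li_constr) %in% G_CLASS) else 0L

  if (!is.na(li_pdne)) {
    a <- pair_at(li_pdne)
    # Construct-class alleles disrupt the haplosufficient host gene.  The
    # dominant-negative edit's cost is entirely captured by s_edit/h_edit
    # (its product retains host-gene function: an edit homozygote pays
    # s_edit, not recessive lethality), whereas recessive-class edits are
    # plain nulls of the host gene.  In a female-specific design
    # (doublesex-like target) edits sit in a female-specific transcript and
    # are fully functional, cost-free alleles in males.
    nonfun <- c(G_CLASS, if (!edits_exempt) "E_rec")
    nonfunctional <- sum(a %in% nonfun)
    if (nonfunctional == 2L) pay(1 - params$s_construct, params$timing_construct)
    if (nG == 1L) pay(1 - params$h_construct * params$s_construct,
                      params$timing_construct)
    n_ed <- sum(a == "E_dom")
    if (n_ed > 0L && !edits_exempt)
      pay(dominant_cost(n_ed, params$s_edit, params$h_edit), params$timing_edit)
  }

  if (!is.na(li_pc)) {
    if (nG == 2L) pay(1 - params$s_construct, params$timing_construct)
    if (nG == 1L) pay(1 - params$h_construct * params$s_construct,
                      params$timing_construct)
    li_hi <- arch_locus(arch, "hi_target")
    if (!is.na(li_hi)) {
      doses <- sum(pair_at(li_hi) == "Wb") + nG
      if (doses < 2L && !edits_exempt)
        pay(1 - params$s_edit, params$timing_edit)
    }
  }

  li_le <- arch_locus(arch, "lethal")
  if (!is.na(li_le)) {
    n_l <- sum(pair_at(li_le) == "L")
    if (n_l > 0L && !(is_male && arch$lethal_sex == "female") && !edits_exempt)
      pay(dominant_cost(n_l, params$s_edit, params$h_edit), params$timing_edit)
  }

  li_fs <- arch_locus(arch, "fsrd")
  if (!is.na(li_fs)) {
    n_d <- sum(pair_at(li_fs) == "Df")
    if (n_d > 0L && !is_male)   # dominant cost in females only, by design
      pay(dominant_cost(n_d, params$s_edit, params$h_edit), params$timing_edit)
  }

  sl <- arch_sex_locus(arch)
  if (!is.na(sl)) {
    n_xe <- sum(pair_at(sl) == "X_edit")
    if (n_xe > 0L && !is_male)
      pay(dominant_cost(n_xe, params$s_edit, params$h_edit), params$timing_edit)
  }

  li_h2 <- arch_locus(arch, "hs2_target")
  if (!is.na(li_h2)) {
    doses <- sum(pair_at(li_h2) == "Wd") + nG
    if (doses == 0L && !is_male) pay(0, params$timing_edit)
  }

  if (any(comp < -1e-12 | comp > 1 + 1e-12))
    stop("internal error: survival probability outside [0, 1]", call. = FALSE)
  comp <- pmin(pmax(comp, 0), 1)
  list(early_survival = comp[["early"]], late_survival = comp[["late"]],
       fertility = comp[["fertility"]])
}
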