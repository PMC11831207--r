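# Gamete formation --------------------------------------------------------
#
# Gametes are produced in three stages: (1) Mendelian segregation with
# recombination between adjacent loci, (2) germline modifications whose
# activity depends on the *parent's* diploid genotype (editing, homing,
# X-shredding) and (3) per-gamete loss-of-function mutation of construct
# components.  All modifications act on expected gamete frequencies; the
# engine is fully deterministic.

#' Gamete distribution of a parent genotype
#'
#' Computes the expected distribution of gamete haplotypes produced by a
#' diploid parent, including germline editing at rate `u`, homing (from a
#' booster or an fs-RIDL-drive element), X-shredding, recombination and
#' loss-of-function mutation of construct components.
#'
#' @param genotype A genotype key (see [geno_key()]) or the parsed list form.
#' @param arch A `gd_architecture`.
#' @param params A [genetic_params()] object.
#' @return Named numeric vector of probabilities over haplotype keys,
#'   summing to 1.
#' @export
gamete_distribution <- function(genotype, arch, params) {
  g <- if (is.character(genotype)) geno_parse(genotype) else genotype
  check_genotype(g, arch)
  validate_genetic_params(params)

  n <- arch$n_loci
  # recombination fraction between locus i and i+1; the sex pair is unlinked
  if (n > 1L) {
    n_adj <- n - 1L
    r <- rep_len(params$recomb_r, max(n_adj, 1L))
    if (arch$sex_chromosome) r[n_adj] <- 0.5
  } else r <- numeric(0)

  # Mendelian segregation with recombination: enumerate 2^n parental-origin
  # patterns; P(pattern) = 1/2 * prod(switch ? r : 1 - r).
  pat <- as.matrix(expand.grid(rep(list(1:2), n)))
  pr <- rep(0.5, nrow(pat))
  if (n > 1L) for (k in 2:n) {
    sw <- pat[, k] != pat[, k - 1L]
    pr <- pr * ifelse(sw, r[k - 1L], 1 - r[k - 1L])
  }
  hm <- matrix("", nrow(pat), n)
  for (k in seq_len(n)) hm[, k] <- ifelse(pat[, k] == 1L, g$h1[k], g$h2[k])
  gam <- collapse_gametes(hm, pr)

  gam <- apply_germline_mods(gam, g, arch, params)

  out <- gam$pr
  names(out) <- apply(gam$hm, 1L, paste, collapse = ":")
  out <- tapply_sum(out)
  # prune numerically negligible gametes, then renormalize
  out <- out[out > 1e-15]
  out / sum(out)
}

collapse_gametes <- function(hm, pr) {
  if (!is.matrix(hm)) hm <- matrix(hm, ncol = 1L)
  key <- apply(hm, 1L, paste, collapse = ":")
  keep <- !duplicated(key)
  pr2 <- as.numeric(tapply(pr, key, sum)[key[keep]])
  list(hm = hm[keep, , drop = FALSE], pr = pr2)
}

tapply_sum <- function(x) {
  if (!anyDuplicated(names(x))) return(x)
  s <- tapply(x, names(x), sum)
  out <- as.numeric(s)
  names(out) <- names(s)
  out
}

# Split rows of a gamete table: for rows selected by `sel`, replace the
# allele at locus `locus` according to `outcomes` (named prob vector whose
# names are replacement alleles; "" means keep the current allele).
split_rows <- function(gam, sel, locus, outcomes) {
  if (!any(sel)) return(gam)
  keep_hm <- gam$hm[!sel, , drop = FALSE]
  keep_pr <- gam$pr[!sel]
  parts_hm <- list(keep_hm)
  parts_pr <- list(keep_pr)
  for (j in seq_along(outcomes)) {
    p <- outcomes[j]
    if (p <= 0) next
    hmj <- gam$hm[sel, , drop = FALSE]
    if (nzchar(names(outcomes)[j])) hmj[, locus] <- names(outcomes)[j]
    parts_hm[[length(parts_hm) + 1L]] <- hmj
    parts_pr[[length(parts_pr) + 1L]] <- gam$pr[sel] * p
  }
  collapse_gametes(do.call(rbind, parts_hm), unlist(parts_pr))
}

apply_germline_mods <- function(gam, g, arch, params) {
  alleles2 <- c(g$h1, g$h2)
  li_pdne <- arch_locus(arch, "pdne")
  li_pc <- arch_locus(arch, "pdne_construct")
  li_constr <- if (!is.na(li_pdne)) li_pdne else li_pc
  sl <- arch_sex_locus(arch)

  # Parent-level editor status.  Editing requires a single construct allele
  # with both Cas9 and gRNA functional; the homing booster and the
  # cleave-and-rescue booster only need a functional Cas9 source.
  constr_alleles <- if (!is.na(li_constr))
    intersect(c(g$h1[li_constr], g$h2[li_constr]), G_CLASS) else character(0)
  editor_ok <- "G" %in% constr_alleles
  cas9_ok <- any(vapply(constr_alleles,
                        function(a) "cas9" %in% G_COMPONENTS[[a]], logical(1)))
  is_male <- identical(g$sex, "M")

  edit_outcomes <- function(edit_allele, rec_allele = NULL) {
    u <- params$u
    fr <- params$frac_recessive
    out <- c(1 - u, u * (1 - fr))
    names(out) <- c("", edit_allele)
    if (fr > 0) {
      if (is.null(rec_allele))
        stop("recessive-class edits are not defined for this locus",
             call. = FALSE)
      out <- c(out, stats::setNames(u * fr, rec_allele))
    }
    out
  }

  # 1. Homing of the construct locus, enabled by the homing booster: cleaved
  #    wild-type alleles convert to the parent's construct allele with
  #    probability homing_rate, and are restored to wild type otherwise.
  li_hb <- arch_locus(arch, "homing_booster")
  if (!is.na(li_hb) && !is.na(li_constr) && cas9_ok &&
      "H_homing" %in% alleles2[c(li_hb, li_hb + arch$n_loci)] &&
      params$homing_rate > 0 && length(constr_alleles)) {
    donor <- constr_alleles[1]
    sel <- gam$hm[, li_constr] == "W"
    gam <- split_rows(gam, sel, li_constr,
                      stats::setNames(c(1 - params$homing_rate,
                                        params$homing_rate), c("", donor)))
  }

  # 2. Germline editing by the construct's own gRNA.
  if (editor_ok && params$u > 0) {
    if (!is.na(li_pdne)) {             # single-locus design: target in cis
      sel <- gam$hm[, li_pdne] == "W"
      gam <- split_rows(gam, sel, li_pdne, edit_outcomes("E_dom", "E_rec"))
    }
    li_hi <- arch_locus(arch, "hi_target")
    if (!is.na(li_hi)) {               # two-locus design: HI target gene
      if (params$frac_recessive > 0)
        stop("frac_recessive is only supported for the single-locus design",
             call. = FALSE)
      sel <- gam$hm[, li_hi] == "Wb"
      gam <- split_rows(gam, sel, li_hi, edit_outcomes("Eb"))
    }
  }

  # 3. Cleave-and-rescue booster: its gRNA directs the construct's Cas9 to a
  #    second haplosufficient gene.
  li_cb <- arch_locus(arch, "cnr_booster")
  li_h2 <- arch_locus(arch, "hs2_target")
  if (!is.na(li_cb) && !is.na(li_h2) && cas9_ok && params$u > 0 &&
      "B_cnr" %in% alleles2[c(li_cb, li_cb + arch$n_loci)]) {
    sel <- gam$hm[, li_h2] == "Wd"
    gam <- split_rows(gam, sel, li_h2,
                      stats::setNames(c(1 - params$u, params$u), c("", "Ed2")))
  }

  # 4. Y-linked editor: carrier males convert transmitted X chromosomes into
  #    dominant female-lethal edited X's at rate u.
  if (!is.na(sl) && is_male && "Y_editor" %in% alleles2[c(sl, sl + arch$n_loci)] &&
      params$u > 0) {
    sel <- gam$hm[, sl] == "X"
    gam <- split_rows(gam, sel, sl,
                      stats::setNames(c(1 - params$u, params$u),
                                      c("", "X_edit")))
  }

  # 5. fs-RIDL-drive: the female-lethal element homes in the male germline.
  li_fs <- arch_locus(arch, "fsrd")
  if (!is.na(li_fs) && is_male && params$homing_rate > 0 &&
      "Df" %in% alleles2[c(li_fs, li_fs + arch$n_loci)]) {
    sel <- gam$hm[, li_fs] == "Wf"
    gam <- split_rows(gam, sel, li_fs,
                      stats::setNames(c(1 - params$homing_rate,
                                        params$homing_rate), c("", "Df")))
  }

  # 6. Loss-of-function mutation: each functional component of a construct
  #    allele is lost independently with probability mu_lof.
  if (!is.na(li_constr) && params$mu_lof > 0) {
    mu <- params$mu_lof
    # derivatives first, so rows newly created from G are not mutated twice
    for (a in c("G_dCas9", "G_dgRNA", "G")) {
      comps <- G_COMPONENTS[[a]]
      sel <- gam$hm[, li_constr] == a
      if (!any(sel)) next
      if (length(comps) == 2L) {
        out <- c((1 - mu)^2,
                 stats::setNames(mu * (1 - mu), lof_transition(a, "cas9")),
                 stats::setNames((1 - mu) * mu, lof_transition(a, "grna")),
                 stats::setNames(mu^2, "G_dBoth"))
        names(out)[1] <- ""
      } else {
        out <- stats::setNames(c(1 - mu, mu), c("", lof_transition(a, comps)))
      }
      gam <- split_rows(gam, sel, li_constr, out)
    }
  }

  # 7. X-shredding in males carrying the shredder: X-bearing gametes are
  #    destroyed at shred_rate; surviving sperm are renormalized.
  li_sh <- arch_locus(arch, "shredder")
  if (!is.na(li_sh) && !is.na(sl) && is_male && params$shred_rate > 0 &&
      "S" %in% alleles2[c(li_sh, li_sh + arch$n_loci)]) {
    xsel <- gam$hm[, sl] %in% c("X", "X_edit")
    gam$pr[xsel] <- gam$pr[xsel] * (1 - params$shred_rate)
    tot <- sum(gam$pr)
    if (tot <= 0) stop("X-shredding removed all gametes", call. = FALSE)
    gam$pr <- gam$pr / tot
  }

  gam
}

#' Offspring genotype distribution of a mating pair
#'
#' Outer product of the two parents' gamete distributions.  Offspring sex is
#' assigned by sex-chromosome inheritance when a sex pair is modeled, and
#' 50:50 otherwise.  A sterile parent (fertility 0) yields an empty
#' distribution with attribute `sterile = TRUE` rather than an error.
#'
#' @inheritParams gamete_distribution
#' @param mother,father Genotype keys; the mother must be female and the
#'   father male.
#' @return Named numeric vector over genotype keys summing to 1, or an empty
#'   vector flagged `sterile` if either parent is infertile.
#' @export
offspring_distribution <- function(mother, father, arch, params) {
  gm <- if (is.character(mother)) geno_parse(mother) else mother
  gf <- if (is.character(father)) geno_parse(father) else father
  if (gm$sex != "F" || gf$sex != "M")
    stop("mother must be female and father male", call. = FALSE)
  vm <- viability(mother, arch, params)
  vf <- viability(father, arch, params)
  if (vm$fertility <= 0 || vf$fertility <= 0)
    return(structure(stats::setNames(numeric(0), character(0)),
                     sterile = TRUE))

  mg <- gamete_distribution(gm, arch, params)
  fg <- gamete_distribution(gf, arch, params)
  sl <- arch_sex_locus(arch)

  out <- numeric(0)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(mg)) {
    hi <- hap_parse(names(mg)[i])
    for (j in seq_along(fg)) {
      hj <- hap_parse(names(fg)[j])
      p <- mg[[i]] * fg[[j]]
      if (!is.na(sl)) {
        sex <- if (hj[sl] %in% c("Y", "Y_editor")) "M" else "F"
        k <- geno_key(hi, hj, sex)
        acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + p
      } else {
        for (sex in c("F", "M")) {
          k <- geno_key(hi, hj, sex)
          acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + p / 2
        }
      }
    }
  }
  ks <- ls(acc)
  out <- vapply(ks, function(k) acc[[k]], numeric(1))
  out / sum(out)
}
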