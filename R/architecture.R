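# Locus architectures -----------------------------------------------------
#
# A genetic architecture is an ordered list of loci (plus an optional sex
# chromosome, always last).  Each locus has a role that determines which
# alleles exist there and how gametes and viability treat them:
#
#   pdne            single-locus protected dominant-negative editor:
#                   W, G (construct), LOF derivatives G_dCas9/G_dgRNA/G_dBoth,
#                   E_dom (dominant-negative edit), E_rec (recessive edit)
#   pdne_construct  two-locus design, construct-bearing haplosufficient gene:
#                   W, G and LOF derivatives (the G haplotype carries a
#                   recoded rescue copy of the haploinsufficient target)
#   hi_target       two-locus design, haploinsufficient target gene: Wb, Eb
#   homing_booster  gRNA-only booster enabling the construct to home: Wc,
#                   H_homing
#   cnr_booster     gRNA-only cleave-and-rescue booster: Wc, B_cnr
#   hs2_target      second haplosufficient gene cut by the cnr booster and
#                   rescued by the construct: Wd, Ed2
#   lethal          dominant lethal cassette (SIT/RIDL/fsRIDL, and the
#                   Y-linked editor's target when carried on the X): Wl, L
#   fsrd            fs-RIDL-drive element: Wf, Df (dominant female lethal
#                   that homes in the male germline)
#   shredder        autosomal X-shredder: Ws, S
#
# Sex chromosome alleles: X, X_edit (dominant female-lethal edit created by a
# Y-linked editor), Y, Y_editor.

LOCUS_ALLELES <- list(
  pdne           = c("W", "G", "G_dCas9", "G_dgRNA", "G_dBoth", "E_dom", "E_rec"),
  pdne_construct = c("W", "G", "G_dCas9", "G_dgRNA", "G_dBoth"),
  hi_target      = c("Wb", "Eb"),
  homing_booster = c("Wc", "H_homing"),
  cnr_booster    = c("Wc", "B_cnr"),
  hs2_target     = c("Wd", "Ed2"),
  lethal         = c("Wl", "L"),
  fsrd           = c("Wf", "Df"),
  shredder       = c("Ws", "S")
)
SEX_ALLELES <- c("X", "X_edit", "Y", "Y_editor")

# Construct-class alleles (carry the insert disrupting the HS gene; LOF
# derivatives keep the disruption and, in two-locus designs, the rescue copy).
G_CLASS <- c("G", "G_dCas9", "G_dgRNA", "G_dBoth")
# Functional molecular components per construct-class allele.
G_COMPONENTS <- list(
  G        = c("cas9", "grna"),
  G_dCas9  = "grna",
  G_dgRNA  = "cas9",
  G_dBoth  = character(0)
)
# Allele resulting from loss of one named component.
lof_transition <- function(allele, component) {
  comps <- setdiff(G_COMPONENTS[[allele]], component)
  for (a in G_CLASS) if (setequal(G_COMPONENTS[[a]], comps)) return(a)
  stop("internal error: no LOF derivative for ", allele)
}

#' Define a genetic architecture
#'
#' @param roles Character vector of locus roles, in chromosome order (see
#'   `LOCUS_ALLELES` for the vocabulary).
#' @param sex_chromosome Logical: model an X/Y pair (always the last,
#'   unlinked, locus)?
#' @param lethal_sex For `lethal` and `fsrd` loci: `"both"` or `"female"`,
#'   which sex pays the dominant cost.
#' @return An object of class `gd_architecture`.
#' @keywords internal
gd_architecture <- function(roles, sex_chromosome = FALSE,
                            lethal_sex = "both") {
  bad <- setdiff(roles, names(LOCUS_ALLELES))
  if (length(bad))
    stop("unknown locus role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  loci <- lapply(seq_along(roles), function(i) {
    list(index = i, role = roles[i], alleles = LOCUS_ALLELES[[roles[i]]])
  })
  if (sex_chromosome) {
    loci[[length(loci) + 1L]] <- list(index = length(loci) + 1L,
                                      role = "sex", alleles = SEX_ALLELES)
  }
  structure(list(loci = loci, roles = roles,
                 n_loci = length(loci),
                 sex_chromosome = sex_chromosome,
                 lethal_sex = match.arg(lethal_sex, c("both", "female"))),
            class = "gd_architecture")
}

arch_locus <- function(arch, role) {
  i <- which(arch$roles == role)
  if (length(i) != 1L) return(NA_integer_)
  i
}
arch_sex_locus <- function(arch) {
  if (arch$sex_chromosome) arch$n_loci else NA_integer_
}

# Haplotype and genotype string codecs ------------------------------------
# A haplotype is a character vector, one allele per locus; its key joins the
# alleles with ":".  A genotype key is the two haplotype keys, sorted, joined
# with "/", plus "|F" or "|M".

hap_key <- function(h) paste(h, collapse = ":")
hap_parse <- function(key) strsplit(key, ":", fixed = TRUE)[[1]]

geno_key <- function(h1, h2, sex) {
  ks <- sort(c(hap_key(h1), hap_key(h2)))
  paste0(ks[1], "/", ks[2], "|", sex)
}
geno_parse <- function(key) {
  sex <- substr(key, nchar(key), nchar(key))
  body <- substr(key, 1, nchar(key) - 2L)
  haps <- strsplit(body, "/", fixed = TRUE)[[1]]
  list(h1 = hap_parse(haps[1]), h2 = hap_parse(haps[2]), sex = sex)
}

# Validate that every allele of a genotype belongs to its locus alphabet and
# that sex is consistent with sex-chromosome alleles.
check_genotype <- function(g, arch) {
  for (h in list(g$h1, g$h2)) {
    if (length(h) != arch$n_loci)
      stop("genotype has ", length(h), " loci; architecture has ",
           arch$n_loci, call. = FALSE)
    for (i in seq_len(arch$n_loci))
      if (!h[i] %in% arch$loci[[i]]$alleles)
        stop("unknown allele symbol `", h[i], "` at locus ", i,
             " (role ", arch$loci[[i]]$role, ")", call. = FALSE)
  }
  if (arch$sex_chromosome) {
    sl <- arch_sex_locus(arch)
    ys <- sum(c(g$h1[sl], g$h2[sl]) %in% c("Y", "Y_editor"))
    expected <- if (ys == 0L) "F" else if (ys == 1L) "M" else
      stop("YY genotype is not viable input", call. = FALSE)
    if (g$sex != expected)
      stop("sex `", g$sex, "` inconsistent with sex-chromosome alleles",
           call. = FALSE)
  }
  invisible(g)
}

# Wild-type haplotype for an architecture (autosomal part).
wild_hap <- function(arch, sex_allele = NULL) {
  h <- vapply(arch$loci, function(l) l$alleles[1], character(1))
  if (arch$sex_chromosome && !is.null(sex_allele))
    h[arch_sex_locus(arch)] <- sex_allele
  h
}

wild_genotypes <- function(arch) {
  if (arch$sex_chromosome) {
    c(F = geno_key(wild_hap(arch, "X"), wild_hap(arch, "X"), "F"),
      M = geno_key(wild_hap(arch, "X"), wild_hap(arch, "Y"), "M"))
  } else {
    h <- wild_hap(arch)
    c(F = geno_key(h, h, "F"), M = geno_key(h, h, "M"))
  }
}
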