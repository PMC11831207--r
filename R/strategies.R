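# Strategy factory ---------------------------------------------------------

STRATEGY_NAMES <- c("sit", "ridl", "fsridl", "xs", "yle", "fsridl_drive",
                    "pdne1", "pdne2")

#' Build a release strategy
#'
#' Maps a strategy name plus options to a complete genetic architecture,
#' parameter set and release genotype.  The parameter baseline is the
#' idealized case (perfect genetic efficiencies, no unintended fitness
#' costs, all deaths after density-dependent mortality); pass individual
#' parameter overrides through `...` to deviate from it.
#'
#' Recognized names:
#' * `"sit"` — sterile males: released males are homozygous for a dominant
#'   lethal acting in both sexes *before* density-dependent mortality.
#' * `"ridl"` — the same, acting *after* density-dependent mortality.
#' * `"fsridl"` — female-specific late-acting dominant lethal.
#' * `"xs"` — autosomal X-shredder: released homozygous males transmit
#'   Y-bearing gametes at `shred_rate`; sons inherit the shredder.
#' * `"yle"` — Y-linked editor: carrier males convert transmitted X's into
#'   dominant female-lethal edits at rate `u`; sons carry the editor.
#' * `"fsridl_drive"` — autosomal dominant female lethal that homes in the
#'   male germline at `homing_rate`; released males are heterozygous
#'   (`release = "hom"` for homozygous).
#' * `"pdne1"` — single-locus protected dominant-negative editor; released
#'   males are heterozygous.
#' * `"pdne2"` — two-locus design: construct inserted in a haplosufficient
#'   gene, carrying a recoded rescue copy of the haploinsufficient target
#'   gene edited by the construct's editor.
#'
#' Boosters (PDNE only): `booster = "homing"` adds a locus carrying a gRNA
#' that lets the construct home at `homing_rate` wherever its Cas9 is
#' present; `booster = "cnr"` adds a linked cleave-and-rescue booster
#' (default `booster_r = 0.05`) whose gRNA directs the construct's Cas9 to a
#' second haplosufficient gene that the construct rescues, with the edit
#' costs female-specific as in the reference configuration.
#'
#' @param name Strategy name (see above).
#' @param ... Overrides of [genetic_params()] fields (e.g. `u = 0.9`,
#'   `timing = "early"`, `sex_limited_edit = "female_only"`).
#' @param booster `"none"`, `"homing"` or `"cnr"` (PDNE strategies only).
#' @param booster_copies 1 or 2 booster copies in released males.
#' @param booster_r Recombination fraction between construct and booster
#'   locus (default 0.5 for the homing booster, 0.05 for cleave and rescue).
#' @param release `"het"` or `"hom"`: zygosity of released fs-RIDL-drive or
#'   PDNE males (strategies whose canonical release is heterozygous).
#' @return An object of class `gd_strategy`: list with `name`, `arch`,
#'   `params`, `release_genotype`, `options`.
#' @examples
#' make_strategy("pdne1")
#' make_strategy("pdne1", u = 0.8, sex_limited_edit = "female_only")
#' make_strategy("pdne1", booster = "homing", booster_copies = 2)
#' @export
make_strategy <- function(name, ...,
                          booster = c("none", "homing", "cnr"),
                          booster_copies = 1L,
                          booster_r = NULL,
                          release = c("het", "hom")) {
  name <- match.arg(tolower(name), STRATEGY_NAMES)
  booster <- match.arg(booster)
  release <- match.arg(release)
  overrides <- list(...)
  if (booster != "none" && !name %in% c("pdne1", "pdne2"))
    stop("booster requested without a PDNE strategy", call. = FALSE)
  if (booster != "none" && name == "pdne2")
    stop("boosters are implemented for the single-locus PDNE only",
         call. = FALSE)
  if (!booster_copies %in% 1:2)
    stop("booster_copies must be 1 or 2", call. = FALSE)

  base <- switch(
    name,
    sit = list(arch = gd_architecture("lethal"),
               params = idealized_params(timing = "early",
                                         u = 0, homing_rate = 0, shred_rate = 0),
               rel = geno_key("L", "L", "M")),
    ridl = list(arch = gd_architecture("lethal"),
                params = idealized_params(u = 0, homing_rate = 0,
                                          shred_rate = 0),
                rel = geno_key("L", "L", "M")),
    fsridl = list(arch = gd_architecture("lethal", lethal_sex = "female"),
                  params = idealized_params(u = 0, homing_rate = 0,
                                            shred_rate = 0),
                  rel = geno_key("L", "L", "M")),
    xs = list(arch = gd_architecture("shredder", sex_chromosome = TRUE),
              params = idealized_params(u = 0, homing_rate = 0,
                                        s_construct = 0),
              rel = geno_key(c("S", "X"), c("S", "Y"), "M")),
    yle = list(arch = gd_architecture(character(0), sex_chromosome = TRUE),
               params = idealized_params(homing_rate = 0, shred_rate = 0,
                                         s_construct = 0),
               rel = geno_key("X", "Y_editor", "M")),
    fsridl_drive = list(
      arch = gd_architecture("fsrd", lethal_sex = "female"),
      params = idealized_params(u = 0, shred_rate = 0, s_construct = 0),
      rel = if (release == "hom") geno_key("Df", "Df", "M")
            else geno_key("Df", "Wf", "M")),
    pdne1 = list(arch = gd_architecture("pdne"),
                 params = idealized_params(homing_rate = 0, shred_rate = 0),
                 rel = if (release == "hom") geno_key("G", "G", "M")
                       else geno_key("G", "W", "M")),
    pdne2 = list(arch = gd_architecture(c("pdne_construct", "hi_target")),
                 params = idealized_params(homing_rate = 0, shred_rate = 0),
                 rel = if (release == "hom")
                         geno_key(c("G", "Wb"), c("G", "Wb"), "M")
                       else geno_key(c("G", "Wb"), c("W", "Wb"), "M"))
  )

  if (booster == "homing") {
    if (is.null(booster_r)) booster_r <- 0.5
    base$arch <- gd_architecture(c("pdne", "homing_booster"))
    base$params <- override_params(base$params,
                                   list(homing_rate = 1, recomb_r = booster_r))
    base$rel <- if (booster_copies == 2L)
      geno_key(c("G", "H_homing"), c("W", "H_homing"), "M")
    else
      geno_key(c("G", "H_homing"), c("W", "Wc"), "M")
  } else if (booster == "cnr") {
    if (is.null(booster_r)) booster_r <- 0.05
    base$arch <- gd_architecture(c("pdne", "cnr_booster", "hs2_target"))
    base$params <- override_params(base$params,
                                   list(recomb_r = c(booster_r, 0.5),
                                        sex_limited_edit = "female_only"))
    base$rel <- if (booster_copies == 2L)
      geno_key(c("G", "B_cnr", "Wd"), c("W", "B_cnr", "Wd"), "M")
    else
      geno_key(c("G", "B_cnr", "Wd"), c("W", "Wc", "Wd"), "M")
  }

  params <- override_params(base$params, overrides)
  structure(list(name = name, arch = base$arch, params = params,
                 release_genotype = base$rel,
                 options = list(booster = booster,
                                booster_copies = booster_copies,
                                booster_r = booster_r,
                                release = release,
                                overrides = overrides)),
            class = "gd_strategy")
}

#' @export
print.gd_strategy <- function(x, ...) {
  cat("<gd_strategy> ", x$name, "\n", sep = "")
  cat("  loci: ", paste(x$arch$roles, collapse = " + "),
      if (x$arch$sex_chromosome) " + sex pair", "\n", sep = "")
  cat("  release genotype: ", x$release_genotype, "\n", sep = "")
  if (x$options$booster != "none")
    cat("  booster: ", x$options$booster, " (", x$options$booster_copies,
        " cop", if (x$options$booster_copies > 1) "ies" else "y",
        ", r = ", x$options$booster_r, ")\n", sep = "")
  ov <- x$options$overrides
  if (length(ov))
    cat("  parameter overrides: ",
        paste(names(ov), unlist(ov), sep = " = ", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
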