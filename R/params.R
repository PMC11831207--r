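#' Genetic parameters of a construct
#'
#' Bundles every tunable molecular property of a genetic-control construct:
#' germline editing, fitness costs of the edit and of the construct itself,
#' timing of the genetic deaths relative to density-dependent juvenile
#' mortality, sex limitation, homing, X-shredding, recombination and
#' loss-of-function (LOF) mutation of the construct components.
#'
#' All probabilities are per-generation and lie in `[0, 1]`.
#'
#' @param u Probability that the germline editor converts a wild-type target
#'   allele into an edit, per allele per germline.
#' @param s_edit Fitness cost of the dominant edit when homozygous (1 =
#'   lethal/sterile).
#' @param h_edit Dominance coefficient of the edit: heterozygotes pay
#'   `h_edit * s_edit`.
#' @param frac_recessive Fraction of edits that are plain recessive
#'   loss-of-function alleles of the disrupted gene rather than
#'   dominant-negative edits.
#' @param s_construct Fitness cost of the construct when both copies of the
#'   disrupted haplosufficient gene are nonfunctional (recessive lethality of
#'   the insert).
#' @param h_construct Dominance coefficient of the construct itself (leaky
#'   expression / insertion-site costs paid by heterozygotes).
#' @param mu_lof Probability, per generation and per molecular component
#'   (Cas9, gRNA), that the component loses function during gamete formation.
#' @param timing Convenience: sets both `timing_edit` and `timing_construct`.
#'   One of `"early"` (deaths before density-dependent mortality), `"late"`
#'   (after it) or `"fertility"` (costs paid as reduced fertility).
#' @param timing_edit,timing_construct Timing of the edit-borne and
#'   construct-borne costs separately; default both from `timing`.
#' @param sex_limited_edit `"both"` or `"female_only"`: whether the dominant
#'   edit costs are paid by both sexes or by females only.
#' @param homing_rate Probability that a cleaved wild-type allele at the
#'   construct locus is converted to the construct by homology-directed
#'   repair (used by the homing booster and by fs-RIDL-drive).
#' @param shred_rate Probability that an X-bearing gamete of a shredder
#'   male is destroyed.
#' @param recomb_r Recombination fraction(s) between adjacent autosomal loci
#'   (each in `[0, 0.5]`); recycled to the number of adjacent pairs.
#'
#' @return An object of class `genetic_params` (a validated list).
#' @examples
#' genetic_params(u = 1, s_edit = 1, h_edit = 1, s_construct = 1)
#' @export
genetic_params <- function(u = 0,
                           s_edit = 0, h_edit = 1, frac_recessive = 0,
                           s_construct = 0, h_construct = 0,
                           mu_lof = 0,
                           timing = c("late", "early", "fertility"),
                           timing_edit = NULL, timing_construct = NULL,
                           sex_limited_edit = c("both", "female_only"),
                           homing_rate = 0, shred_rate = 0,
                           recomb_r = 0.5) {
  timing <- match.arg(timing)
  sex_limited_edit <- match.arg(sex_limited_edit)
  if (is.null(timing_edit)) timing_edit <- timing
  if (is.null(timing_construct)) timing_construct <- timing
  timing_edit <- match.arg(timing_edit, c("late", "early", "fertility"))
  timing_construct <- match.arg(timing_construct, c("late", "early", "fertility"))

  p <- list(u = u, s_edit = s_edit, h_edit = h_edit,
            frac_recessive = frac_recessive,
            s_construct = s_construct, h_construct = h_construct,
            mu_lof = mu_lof,
            timing_edit = timing_edit, timing_construct = timing_construct,
            sex_limited_edit = sex_limited_edit,
            homing_rate = homing_rate, shred_rate = shred_rate,
            recomb_r = recomb_r)
  validate_genetic_params(p)
  class(p) <- "genetic_params"
  p
}

validate_genetic_params <- function(p) {
  probs <- c("u", "s_edit", "h_edit", "frac_recessive", "s_construct",
             "h_construct", "mu_lof", "homing_rate", "shred_rate")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("genetic_params: `", nm, "` must be a single probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(p$recomb_r) || any(is.na(p$recomb_r)) ||
      any(p$recomb_r < 0) || any(p$recomb_r > 0.5))
    stop("genetic_params: `recomb_r` must lie in [0, 0.5]", call. = FALSE)
  invisible(p)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat("<genetic_params>\n")
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1L, logical(1))
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Fully idealized construct parameters: editing always succeeds, edits are
# fully dominant lethals, the insert is a fully penetrant recessive lethal
# with no heterozygous cost, and the construct never mutates.
idealized_params <- function(..., timing = "late") {
  base <- genetic_params(u = 1, s_edit = 1, h_edit = 1, frac_recessive = 0,
                         s_construct = 1, h_construct = 0, mu_lof = 0,
                         timing = timing, homing_rate = 1, shred_rate = 1)
  override_params(base, list(...))
}

# Apply a named list of overrides to a genetic_params object, re-validating.
override_params <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("parameter overrides must be named", call. = FALSE)
  bad <- setdiff(names(overrides), c(names(unclass(p)), "timing"))
  if (length(bad))
    stop("unknown genetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(overrides$timing)) {
    overrides$timing_edit <- overrides$timing
    overrides$timing_construct <- overrides$timing
    overrides$timing <- NULL
  }
  out <- utils::modifyList(unclass(p), overrides)
  validate_genetic_params(out)
  class(out) <- "genetic_params"
  out
}
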