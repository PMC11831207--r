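# S3 methods for simulation results ---------------------------------------

#' @export
print.gd_sim <- function(x, ...) {
  n <- nrow(x$series)
  cat("<gd_sim> ", x$strategy$name, ", Rm = ", x$lc$Rm,
      ", rho = ", x$release$rho, " (", x$release$cadence, "), ",
      x$horizon, " generations\n", sep = "")
  cat(sprintf("  final females (rel.): %.4g   final males (rel.): %.4g\n",
              x$series$females_rel[n], x$series$males_rel[n]))
  sup <- 1 - min(x$series$females_rel[-1]) / x$lc$F0
  if (n > 1) cat(sprintf("  max suppression achieved: %.1f%%\n", 100 * sup))
  invisible(x)
}

#' @export
summary.gd_sim <- function(object, targets = c(0.67, 0.95, 0.99), ...) {
  fp <- vapply(targets, function(tg) {
    g <- first_passage(object, tg)
    if (is.na(g)) NA_real_ else as.numeric(g)
  }, numeric(1))
  out <- list(strategy = object$strategy$name, Rm = object$lc$Rm,
              rho = object$release$rho, horizon = object$horizon,
              final_females = object$series$females_rel[nrow(object$series)],
              first_passage = stats::setNames(fp, paste0(100 * targets, "%")))
  class(out) <- "summary.gd_sim"
  out
}

#' @export
print.summary.gd_sim <- function(x, ...) {
  cat("Simulation of", x$strategy, "releases: Rm =", x$Rm, ", rho =", x$rho,
      "\n")
  cat(sprintf("  final relative female count: %.4g\n", x$final_females))
  cat("  first passage below suppression targets (generation):\n")
  for (nm in names(x$first_passage))
    cat(sprintf("    %s: %s\n", nm,
                ifelse(is.na(x$first_passage[nm]), "not reached",
                       format(x$first_passage[nm]))))
  invisible(x)
}

#' @export
as.data.frame.gd_sim <- function(x, ...) {
  cbind(x$series[, c("generation", "females_rel", "males_rel")],
        as.data.frame(x$allele_freq), load = x$series$load)
}

#' Plot a simulation time course
#'
#' Relative female count over generations, optionally with allele
#' frequencies overlaid.
#'
#' @param x A `gd_sim`.
#' @param what `"females"` or `"freq"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gd_sim <- function(x, what = c("females", "freq"), ...) {
  what <- match.arg(what)
  gen <- x$series$generation
  if (what == "females") {
    graphics::plot(gen, x$series$females_rel, type = "l", lwd = 2,
                   xlab = "generation", ylab = "relative female count",
                   ylim = c(0, max(1, x$series$females_rel)), ...)
    graphics::abline(h = 0.05, lty = 3, col = "grey50")
  } else {
    graphics::matplot(gen, x$allele_freq, type = "l", lty = 1,
                      xlab = "generation", ylab = "allele frequency", ...)
    graphics::legend("topright", legend = colnames(x$allele_freq),
                     col = seq_len(ncol(x$allele_freq)), lty = 1, cex = 0.7)
  }
  invisible(x)
}
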