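#' Two-cohort genetic-vector association analysis
#'
#' Runs the full screening pipeline on two case-control cohorts genotyped
#' on one marker panel: (i) group individuals into genetic-vector tables;
#' (ii) align the cohorts on their common vectors; (iii) set aside zero GVs
#' (groups with no cases or no controls in either cohort); (iv) compute
#' per-group exact odds-ratio statistics against each cohort's
#' randomized-OR null; (v) stratify common non-zero vectors by effect
#' direction; (vi) keep the vectors that clear the `alpha` fluctuation
#' threshold in both cohorts; (vii) average the index matrices of the
#' selected risk cases and protective controls into genotype-content
#' contrast profiles; and (viii) profile the zero GVs separately. Cropping
#' the panel first (argument `crop`) re-runs the analysis on shorter
#' vectors, which is how the markers that drive a contrast are identified.
#'
#' @param a,b The two cohorts: `cohort_genotypes` or ready-made
#'   `gv_table`s (pre-grouped published counts are first-class inputs).
#' @param alpha Per-tail accuracy for the fluctuation thresholds.
#' @param totals `"filtered"` (default) conditions each group's null on the
#'   totals of the analysis set (common, zero-free vectors), `"raw"` on the
#'   full cohort totals.
#' @param crop Optional marker names/positions to keep; vectors are cropped
#'   and merged before the analysis.
#' @param names Length-2 cohort display names.
#' @return An object of class `gva`; see [summary.gva()] and [plot.gva()].
#' @examples
#' cfg <- sim_config(seed = 7, planted_or = c(2, rep(1, 39)), n_gv = 40)
#' pair <- generate_pair(cfg)
#' fit <- gva(pair$a, pair$b)
#' summary(fit)
#' @export
gva <- function(a, b, alpha = 0.05, totals = c("filtered", "raw"),
                crop = NULL, names = c("A", "B")) {
  totals <- match.arg(totals)
  as_table <- function(x) {
    if (inherits(x, "cohort_genotypes")) gv_table(x)
    else if (inherits(x, "gv_table")) x
    else stop("cohorts must be cohort_genotypes or gv_table objects")
  }
  ta <- as_table(a); tb <- as_table(b)
  if (!is.null(crop)) {
    ta <- crop(ta, crop)
    tb <- crop(tb, crop)
  }
  align <- align_cohorts(ta, tb)

  # zero GVs are set aside per cohort; a common GV enters the screening set
  # only if it has both cases and controls in *both* cohorts
  ia <- match(align$common, rownames(ta$states))
  ib <- match(align$common, rownames(tb$states))
  zero_a <- classify_zero(ta$n_h[ia], ta$n_s[ia])
  zero_b <- classify_zero(tb$n_h[ib], tb$n_s[ib])
  nonzero <- zero_a == "none" & zero_b == "none"
  analysis <- align$common[nonzero]
  if (length(analysis) == 0L)
    stop("no common genetic vectors with cases and controls in both cohorts")

  sub_a <- subset_gv_table(ta, analysis,
                           if (totals == "filtered") "subset" else "keep")
  sub_b <- subset_gv_table(tb, analysis,
                           if (totals == "filtered") "subset" else "keep")
  stats_a <- gv_stats(sub_a, alpha)
  stats_b <- gv_stats(sub_b, alpha)

  omega <- stratify_omega(analysis,
                          stats_a$or[match(analysis, stats_a$gv)],
                          stats_b$or[match(analysis, stats_b$gv)])
  selection <- select_consistent(omega, stats_a, stats_b, alpha)

  profile <- function(tab) {
    risk <- if (length(selection$risk) > 0L)
      subset_gv_table(tab, selection$risk, "subset")
    prot <- if (length(selection$protective) > 0L)
      subset_gv_table(tab, selection$protective, "subset")
    out <- list(
      risk_case = if (!is.null(risk)) contrast_average(risk, "s"),
      risk_control = if (!is.null(risk)) contrast_average(risk, "h"),
      protective_case = if (!is.null(prot)) contrast_average(prot, "s"),
      protective_control = if (!is.null(prot)) contrast_average(prot, "h"))
    # headline contrast: genotype content of risk-group cases vs
    # protective-group controls
    if (!is.null(out$risk_case) && !is.null(out$protective_control))
      out$diff <- out$risk_case - out$protective_control
    out
  }
  zero_keys_a <- align$common[zero_a != "none"]
  zero_keys_b <- align$common[zero_b != "none"]
  zero <- zero_gv_matrices(
    subset_gv_table(ta, align$common, "keep"),
    subset_gv_table(tb, align$common, "keep"))

  structure(list(
    call = match.call(), names = names, alpha = alpha, totals = totals,
    panel = ta$panel, tables = list(a = ta, b = tb), align = align,
    analysis = analysis,
    zero_keys = list(a = zero_keys_a, b = zero_keys_b),
    effective_totals = list(a = c(N_h = sub_a$N_h, N_s = sub_a$N_s),
                            b = c(N_h = sub_b$N_h, N_s = sub_b$N_s)),
    stats = list(a = stats_a, b = stats_b),
    omega = omega, selection = selection,
    contrast = list(a = profile(ta), b = profile(tb)),
    zero = zero),
    class = "gva")
}

#' @export
print.gva <- function(x, ...) {
  cat("Genetic-vector association analysis\n")
  cat(sprintf("  cohorts: %s (%d GVs), %s (%d GVs); %d common, %d screened\n",
              x$names[1L], nrow(x$tables$a$states),
              x$names[2L], nrow(x$tables$b$states),
              length(x$align$common), length(x$analysis)))
  cat(sprintf("  consistent at alpha = %g: %d risk, %d protective GV(s)\n",
              x$alpha, length(x$selection$risk),
              length(x$selection$protective)))
  invisible(x)
}

#' Summarize a genetic-vector association analysis
#'
#' @param object A `gva` fit.
#' @param ... Unused.
#' @return An object of class `summary.gva` printing alignment, zero-GV,
#'   stratification and selection summaries plus the headline contrast
#'   matrix difference.
#' @export
summary.gva <- function(object, ...) {
  structure(list(fit = object), class = "summary.gva")
}

#' @export
print.summary.gva <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nAlignment (GV groups / controls / cases):\n")
  print(f$align$counts)
  cat(sprintf("\nZero GVs among common (excluded from screening): %d in %s, %d in %s\n",
              length(f$zero_keys$a), f$names[1L],
              length(f$zero_keys$b), f$names[2L]))
  cat(sprintf("Screening totals (%s): %s N_h = %d, N_s = %d; %s N_h = %d, N_s = %d\n",
              f$totals, f$names[1L], f$effective_totals$a["N_h"],
              f$effective_totals$a["N_s"], f$names[2L],
              f$effective_totals$b["N_h"], f$effective_totals$b["N_s"]))
  cat("\n")
  print(f$omega)
  cat("\n")
  print(f$selection)
  sel <- f$selection$details
  sel <- sel[sel$selected, c("gv", "side", "or_a", "or_b", "p_a", "p_b")]
  if (nrow(sel) > 0L) {
    cat("\nSelected GVs (exact tail probabilities per cohort):\n")
    print(sel, row.names = FALSE, digits = 4)
  }
  if (!is.null(f$contrast$a$diff)) {
    cat(sprintf("\n%s genotype-content contrast (risk cases - protective controls):\n",
                f$names[1L]))
    print(round(f$contrast$a$diff, 4))
  }
  invisible(x)
}

#' Plot observed odds ratios against their exact fluctuation bands
#'
#' One panel per cohort: for every screened genetic vector the observed
#' odds ratio (points) is drawn over the `[lower, upper]` threshold
#' interval of its own randomized-OR distribution (vertical segments);
#' points outside their segment are the vectors the selection rule can
#' accept. Vectors are ordered by total frequency in the second cohort.
#'
#' @param x A `gva` fit.
#' @param log Use a log odds-ratio axis (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gva <- function(x, log = TRUE, ...) {
  ord <- order(-(x$stats$b$n_h + x$stats$b$n_s))
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  for (side in c("a", "b")) {
    s <- x$stats[[side]][ord, ]
    n <- nrow(s)
    ylim <- range(c(s$or, s$or_lower_tr, s$or_upper_tr), finite = TRUE)
    if (log) ylim[1L] <- max(ylim[1L], 1e-3)
    graphics::plot(NA, xlim = c(1, n), ylim = ylim,
                   log = if (log) "y" else "",
                   xlab = "", ylab = "odds ratio",
                   main = x$names[if (side == "a") 1L else 2L], ...)
    graphics::segments(seq_len(n), pmax(s$or_lower_tr, ylim[1L]),
                       seq_len(n), s$or_upper_tr, col = "grey60")
    graphics::abline(h = 1, lty = 3)
    out <- s$or > s$or_upper_tr | s$or < s$or_lower_tr
    graphics::points(seq_len(n), s$or, pch = 19,
                     col = ifelse(out, "firebrick", "black"), cex = 0.6)
  }
  invisible(x)
}
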