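#' Align two cohorts on their genetic-vector sets
#'
#' Splits the union of the two tables' genetic vectors into those common to
#' both cohorts and those private to each, with the individual counts each
#' set carries. Only common vectors support cross-cohort comparison;
#' private vectors are typically rare singletons.
#'
#' @param a,b `gv_table`s on the same panel.
#' @return A list with `common`, `a_only`, `b_only` (character keys), and a
#'   `counts` data.frame of group/individual tallies per set and cohort.
#' @export
align_cohorts <- function(a, b) {
  basis <- common_basis(list(a = a, b = b))
  common <- basis$keys[basis$common]
  a_only <- basis$keys[basis$membership[, "a"] & !basis$common]
  b_only <- basis$keys[basis$membership[, "b"] & !basis$common]
  tally <- function(tab, keys) {
    i <- match(keys, rownames(tab$states))
    i <- i[!is.na(i)]
    c(gvs = length(i), n_h = sum(tab$n_h[i]), n_s = sum(tab$n_s[i]))
  }
  counts <- rbind(a_common = tally(a, common), b_common = tally(b, common),
                  a_only = tally(a, a_only), b_only = tally(b, b_only))
  list(common = common, a_only = a_only, b_only = b_only,
       counts = as.data.frame(counts))
}

#' Stratify common genetic vectors by effect direction
#'
#' Partitions common, non-zero genetic vectors into four classes by the
#' direction of effect in each cohort: `omega_11` (odds ratio above 1 in
#' both; consistently risk), `omega_22` (below 1 in both; consistently
#' protective), and the discordant classes `omega_12` / `omega_21`. Risk
#' classes use strict inequalities, so a vector with an odds ratio of
#' exactly 1 in a cohort falls on that cohort's protective side; such
#' boundary cases are counted in the result.
#'
#' @param common Character keys of the common non-zero vectors.
#' @param or_a,or_b Finite odds ratios per vector, aligned with `common`.
#' @return An object of class `omega_partition`: the four key sets and
#'   `boundary`, the number of odds ratios exactly equal to 1.
#' @export
stratify_omega <- function(common, or_a, or_b) {
  if (length(or_a) != length(common) || length(or_b) != length(common))
    stop("'or_a' and 'or_b' must align with 'common'")
  if (anyNA(or_a) || anyNA(or_b) || !all(is.finite(or_a)) ||
      !all(is.finite(or_b)))
    stop("odds ratios must be finite: exclude zero GVs before stratifying")
  up_a <- or_a > 1; up_b <- or_b > 1
  structure(list(
    omega_11 = common[up_a & up_b],
    omega_12 = common[up_a & !up_b],
    omega_21 = common[!up_a & up_b],
    omega_22 = common[!up_a & !up_b],
    boundary = sum(or_a == 1) + sum(or_b == 1)),
    class = "omega_partition")
}

#' @export
print.omega_partition <- function(x, ...) {
  cat("Effect-direction stratification of common GVs:\n")
  cat(sprintf("  omega_11 (risk in both):        %d\n", length(x$omega_11)))
  cat(sprintf("  omega_12 / omega_21 (discordant): %d / %d\n",
              length(x$omega_12), length(x$omega_21)))
  cat(sprintf("  omega_22 (protective in both):  %d\n", length(x$omega_22)))
  if (x$boundary > 0)
    cat(sprintf("  (%d odds ratio(s) exactly 1, assigned protective side)\n",
                x$boundary))
  invisible(x)
}

#' Select cross-cohort consistent contrast groups
#'
#' From the direction-consistent classes, keeps only vectors whose observed
#' odds ratio clears the cohort-specific fluctuation threshold in *both*
#' cohorts: risk vectors (`omega_11`) must exceed the upper `alpha`
#' threshold of their own randomized-OR distribution in each cohort, and
#' protective vectors (`omega_22`) must fall below each cohort's lower
#' threshold. The protective side is judged on the lower tail of the same
#' distribution rather than on a fixed reciprocal of the upper threshold.
#' Exact tail probabilities beyond the observed odds ratio are attached for
#' reporting (commonly plotted as \eqn{-\log_{10} P}); for protective
#' vectors the inverted odds ratio `1 / OR` is also reported.
#'
#' @param partition An `omega_partition`.
#' @param stats_a,stats_b Per-group statistics from [gv_stats()] for each
#'   cohort (computed at that cohort's totals), with `gv` keys covering the
#'   partition.
#' @param alpha Tail accuracy; must match the one used in `gv_stats`.
#' @return An object of class `contrast_selection`: `risk` and `protective`
#'   key vectors and a `details` data.frame with per-vector, per-cohort
#'   odds ratios, thresholds and tail probabilities.
#' @export
select_consistent <- function(partition, stats_a, stats_b, alpha = 0.05) {
  stopifnot(inherits(partition, "omega_partition"))
  pick <- function(stats, keys) stats[match(keys, stats$gv), , drop = FALSE]
  detail <- function(keys, side) {
    if (length(keys) == 0L)
      return(data.frame(gv = character(), side = character(),
                        or_a = numeric(), or_b = numeric(),
                        threshold_a = numeric(), threshold_b = numeric(),
                        p_a = numeric(), p_b = numeric(),
                        selected = logical(), stringsAsFactors = FALSE))
    sa <- pick(stats_a, keys); sb <- pick(stats_b, keys)
    if (anyNA(sa$or) || anyNA(sb$or))
      stop("statistics missing for some partition members")
    if (side == "risk") {
      thr_a <- sa$or_upper_tr; thr_b <- sb$or_upper_tr
      sel <- sa$or > thr_a & sb$or > thr_b
      p_a <- sa$p_upper; p_b <- sb$p_upper
    } else {
      thr_a <- sa$or_lower_tr; thr_b <- sb$or_lower_tr
      sel <- sa$or < thr_a & sb$or < thr_b
      p_a <- sa$p_lower; p_b <- sb$p_lower
    }
    data.frame(gv = keys, side = side, or_a = sa$or, or_b = sb$or,
               threshold_a = thr_a, threshold_b = thr_b,
               p_a = p_a, p_b = p_b, selected = sel,
               stringsAsFactors = FALSE)
  }
  d <- rbind(detail(partition$omega_11, "risk"),
             detail(partition$omega_22, "protective"))
  if (nrow(d) > 0L) {
    inv <- d$side == "protective"
    d$or_inv_a <- ifelse(inv, 1 / d$or_a, NA_real_)
    d$or_inv_b <- ifelse(inv, 1 / d$or_b, NA_real_)
  }
  structure(list(risk = d$gv[d$side == "risk" & d$selected],
                 protective = d$gv[d$side == "protective" & d$selected],
                 details = d, alpha = alpha),
            class = "contrast_selection")
}

#' @export
print.contrast_selection <- function(x, ...) {
  cat(sprintf(
    "Consistent contrast GVs at alpha = %g: %d risk, %d protective\n",
    x$alpha, length(x$risk), length(x$protective)))
  invisible(x)
}

#' Weighted genotype-content average of a contrast group
#'
#' Averages the index matrices of the table's genetic vectors with weights
#' proportional to the chosen group's per-vector counts,
#' \eqn{w_\nu = n_\nu^\alpha / \sum_\nu n_\nu^\alpha}. Applied to a selected
#' contrast subset this gives the genotype-frequency profile of that
#' subset's cases or controls; cells where the case and control profiles
#' differ most point at the markers driving the contrast.
#'
#' @param table A `gv_table`, typically restricted to a selected contrast
#'   set (see [subset_gv_table()]).
#' @param group `"h"` (weights from control counts) or `"s"` (case counts).
#' @return A 3 x N column-stochastic matrix.
#' @export
contrast_average <- function(table, group = c("h", "s")) {
  stopifnot(inherits(table, "gv_table"))
  if (nrow(table$states) == 0L) stop("empty selection")
  frequency_map(table, group)
}

#' Restrict a genetic-vector table to a set of vectors
#'
#' @param table A `gv_table`.
#' @param keys Character keys (dash-joined state tuples) to keep.
#' @param totals `"keep"` retains the parent cohort totals, `"subset"`
#'   resets them to the subset sums.
#' @return A `gv_table`.
#' @export
subset_gv_table <- function(table, keys, totals = c("keep", "subset")) {
  stopifnot(inherits(table, "gv_table"))
  totals <- match.arg(totals)
  i <- match(keys, rownames(table$states))
  if (anyNA(i))
    stop("key(s) not in table: ", paste(keys[is.na(i)], collapse = ", "))
  gv_table_from_counts(table$states[i, , drop = FALSE], table$n_h[i],
                       table$n_s[i], table$panel,
                       N_h = if (totals == "keep") table$N_h else sum(table$n_h[i]),
                       N_s = if (totals == "keep") table$N_s else sum(table$n_s[i]))
}

#' Genotype-content profiles of zero genetic vectors
#'
#' Zero GVs — groups populated solely by cases ("solely sick", SS) or
#' solely by controls ("solely healthy", SH) — admit no odds ratio, but
#' their genotype content can still be contrasted: within each cohort the
#' index matrices of the SS set are averaged with case-count weights and
#' those of the SH set with control-count weights, and the difference
#' SS - SH highlights genotypes tending towards disease (positive cells)
#' or protection (negative cells). With two cohorts, cells whose
#' difference has the same sign in both are flagged as cross-cohort
#' consistent.
#'
#' @param a,b `gv_table`s on the same panel (`b` may be `NULL` for a
#'   single-cohort profile).
#' @return A list with per-cohort entries (`ss`, `sh`, `diff`, counts) and,
#'   when both cohorts are given, `consistent`: a 3 x N logical matrix
#'   (`NA` where either difference is undefined or zero).
#' @export
zero_gv_matrices <- function(a, b = NULL) {
  one <- function(tab) {
    zero <- classify_zero(tab$n_h, tab$n_s)
    ss_keys <- rownames(tab$states)[zero == "solely_sick"]
    sh_keys <- rownames(tab$states)[zero == "solely_healthy"]
    ss <- if (length(ss_keys) > 0L)
      contrast_average(subset_gv_table(tab, ss_keys, "subset"), "s")
    sh <- if (length(sh_keys) > 0L)
      contrast_average(subset_gv_table(tab, sh_keys, "subset"), "h")
    list(ss = ss, sh = sh,
         diff = if (!is.null(ss) && !is.null(sh)) ss - sh,
         n_ss_gv = length(ss_keys), n_sh_gv = length(sh_keys),
         n_ss = sum(tab$n_s[zero == "solely_sick"]),
         n_sh = sum(tab$n_h[zero == "solely_healthy"]))
  }
  res <- list(a = one(a))
  if (!is.null(b)) {
    res$b <- one(b)
    if (!is.null(res$a$diff) && !is.null(res$b$diff)) {
      cons <- sign(res$a$diff) == sign(res$b$diff) & res$a$diff != 0
      cons[res$a$diff == 0 & res$b$diff == 0] <- NA
      res$consistent <- cons
    }
  }
  res
}
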