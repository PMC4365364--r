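#' Configuration for paired synthetic case-control cohorts
#'
#' Describes a pair of cohorts drawn from a shared pool of genetic vectors
#' with heavy-tailed base frequencies, per-vector planted odds ratios, a
#' cross-cohort frequency perturbation, and optionally planted zero GVs.
#' Cases are drawn from base (control) frequencies reweighted per vector by
#' the planted odds ratio and renormalized, so each vector's expected
#' case/control representation matches its planted effect.
#'
#' @param seed Random seed (mandatory; the draw is fully reproducible).
#' @param n_markers Panel length; the last marker is categorical
#'   (No/Single/Double), the rest are SNPs.
#' @param n_gv Number of distinct vectors in the shared pool.
#' @param zipf Power-law exponent of the base frequency ranks (weight of
#'   rank r is proportional to `r^-zipf`); matches the observed structure
#'   of real cohorts, where a few vectors carry most individuals.
#' @param base_weights Optional explicit base weights (length `n_gv`),
#'   overriding the power law.
#' @param planted_or Per-vector odds ratios (length `n_gv`, default all 1).
#' @param N_h,N_s Controls and cases per cohort; length 1 or 2 (cohort A, B).
#' @param perturb Standard deviation of the log-normal perturbation applied
#'   to cohort B's base weights (0 = identical base frequencies).
#' @param zero_ss,zero_sh Numbers of planted zero GVs (case-only /
#'   control-only groups, added identically to both cohorts).
#' @param zero_size Individuals per planted zero GV.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, n_markers = 7L, n_gv = 150L, zipf = 1.0,
                       base_weights = NULL, planted_or = NULL,
                       N_h = 1000L, N_s = 1500L, perturb = 0.2,
                       zero_ss = 0L, zero_sh = 0L, zero_size = 3L) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  if (n_markers < 1L) stop("'n_markers' must be at least 1")
  if (n_gv < 2L) stop("'n_gv' must be at least 2")
  if (n_gv + zero_ss + zero_sh > 3^n_markers)
    stop("more distinct vectors requested than the panel admits")
  if (!is.null(base_weights)) {
    if (length(base_weights) != n_gv || any(base_weights <= 0))
      stop("'base_weights' must be ", n_gv, " positive weights")
  }
  planted_or <- planted_or %||% rep(1, n_gv)
  if (length(planted_or) != n_gv || any(!is.finite(planted_or)) ||
      any(planted_or <= 0))
    stop("'planted_or' must be ", n_gv, " positive finite odds ratios")
  N_h <- rep_len(as.integer(N_h), 2L)
  N_s <- rep_len(as.integer(N_s), 2L)
  if (any(N_h < 1L) || any(N_s < 1L)) stop("cohort sizes must be positive")
  structure(list(seed = as.integer(seed), n_markers = as.integer(n_markers),
                 n_gv = as.integer(n_gv), zipf = zipf,
                 base_weights = base_weights, planted_or = planted_or,
                 N_h = N_h, N_s = N_s, perturb = perturb,
                 zero_ss = as.integer(zero_ss), zero_sh = as.integer(zero_sh),
                 zero_size = as.integer(zero_size)),
            class = "sim_config")
}

#' Generic panel for synthetic cohorts
#'
#' SNP markers `M1 .. M(n-1)` with rotating nucleotide alphabets plus one
#' trailing categorical marker `CAT` (No/Single/Double), exercising the
#' same two marker kinds as a real SNP + shared-epitope panel.
#'
#' @param n_markers Panel length (>= 1).
#' @return A `marker_panel`.
#' @export
synthetic_panel <- function(n_markers = 7L) {
  alphabets <- list(c("AA", "AC", "CC"), c("CC", "CT", "TT"),
                    c("GG", "GT", "TT"), c("AA", "AG", "GG"))
  markers <- vector("list", n_markers)
  for (j in seq_len(n_markers)) {
    markers[[j]] <- if (j == n_markers)
      marker_def("CAT", c("No", "Single", "Double"), kind = "categorical")
    else
      marker_def(paste0("M", j), alphabets[[1L + (j - 1L) %% 4L]])
  }
  marker_panel(markers)
}

draw_unique_tuples <- function(n, n_markers) {
  seen <- character(0)
  out <- matrix(NA_integer_, n, n_markers)
  filled <- 0L
  while (filled < n) {
    cand <- matrix(sample(1:3, (n - filled) * n_markers, replace = TRUE),
                   ncol = n_markers)
    keys <- gv_key(cand)
    keep <- !duplicated(keys) & !(keys %in% seen)
    if (any(keep)) {
      take <- which(keep)
      out[filled + seq_along(take), ] <- cand[take, , drop = FALSE]
      seen <- c(seen, keys[take])
      filled <- filled + length(take)
    }
  }
  out
}

#' Generate a pair of synthetic case-control cohorts
#'
#' Draws the shared vector pool, samples control counts from the base
#' frequencies and case counts from the odds-reweighted frequencies
#' (independently per cohort, cohort B on perturbed base frequencies),
#' plants any requested zero GVs, and expands the counts into
#' per-individual genotype cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with `a`, `b` (`cohort_genotypes`), `panel`, and `truth`:
#'   the pool keys, per-cohort base and case frequencies, planted odds
#'   ratios, planted zero-GV keys, and the drawn per-cohort counts.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- synthetic_panel(config$n_markers)
  n_extra <- config$zero_ss + config$zero_sh
  pool <- draw_unique_tuples(config$n_gv + n_extra, config$n_markers)
  states <- pool[seq_len(config$n_gv), , drop = FALSE]
  zero_states <- pool[config$n_gv + seq_len(n_extra), , drop = FALSE]

  w <- config$base_weights %||% seq_len(config$n_gv)^(-config$zipf)
  p_base <- list(a = w / sum(w), b = NULL)
  wb <- w * exp(stats::rnorm(config$n_gv, 0, config$perturb))
  p_base$b <- wb / sum(wb)

  or <- config$planted_or
  cohorts <- list()
  counts <- list()
  for (i in 1:2) {
    side <- c("a", "b")[i]
    p_h <- p_base[[side]]
    p_s <- p_h * or / sum(p_h * or)
    n_h <- stats::rmultinom(1L, config$N_h[i], p_h)[, 1L]
    n_s <- stats::rmultinom(1L, config$N_s[i], p_s)[, 1L]
    st <- states
    if (n_extra > 0L) {
      st <- rbind(st, zero_states)
      n_h <- c(n_h, rep(c(0L, config$zero_size),
                        c(config$zero_ss, config$zero_sh)))
      n_s <- c(n_s, rep(c(config$zero_size, 0L),
                        c(config$zero_ss, config$zero_sh)))
    }
    counts[[side]] <- list(states = st, n_h = n_h, n_s = n_s)
    cohorts[[side]] <- expand_cohort(st, n_h, n_s, panel,
                                     prefix = toupper(side))
  }
  truth <- list(
    keys = gv_key(states), p_base = p_base, planted_or = or,
    zero_ss_keys = if (config$zero_ss > 0L)
      gv_key(zero_states[seq_len(config$zero_ss), , drop = FALSE]),
    zero_sh_keys = if (config$zero_sh > 0L)
      gv_key(zero_states[config$zero_ss + seq_len(config$zero_sh), ,
                         drop = FALSE]),
    counts = counts)
  list(a = cohorts$a, b = cohorts$b, panel = panel, truth = truth,
       config = config)
}

# expand per-GV counts into one row per individual, controls first
expand_cohort <- function(states, n_h, n_s, panel, prefix = "X") {
  keep <- n_h + n_s > 0L
  states <- states[keep, , drop = FALSE]
  n_h <- n_h[keep]; n_s <- n_s[keep]
  idx <- c(rep(seq_len(nrow(states)), n_h), rep(seq_len(nrow(states)), n_s))
  pheno <- rep(c(0L, 1L), c(sum(n_h), sum(n_s)))
  labels <- matrix(NA_character_, length(idx), ncol(states))
  for (j in seq_len(ncol(states)))
    labels[, j] <- panel[[j]]$states[states[idx, j]]
  cohort_genotypes(sprintf("%s%05d", prefix, seq_along(idx)), labels,
                   pheno, panel)
}

#' Published rheumatoid-arthritis contrast fixtures
#'
#' The consistency-selected contrast genetic-vector groups reported for two
#' independent rheumatoid-arthritis case-control cohorts (EIRA and NARAC)
#' on the 7-marker HTR2A + shared-epitope panel: six risk groups (odds
#' ratio above threshold in both cohorts) and eight protective groups,
#' with per-group control/case counts and the post-filter cohort totals
#' (EIRA 779 controls / 1500 cases; NARAC 866 / 711). Also carries the
#' worked odds-ratio example used throughout the documentation: a group of
#' 4 controls and 33 cases screened against the EIRA totals.
#'
#' @return A list with `panel`, `risk` and `protective` (each a list of
#'   `gv_table`s `eira` and `narac`), and `or_example`
#'   (`N_h`, `N_s`, `n_h`, `n_s`).
#' @examples
#' fx <- contrast_fixtures()
#' sum(fx$risk$eira$n_s)         # 204 cases in the risk groups
#' contrast_average(fx$risk$eira, "s")["gamma1", "rs977003"]
#' @export
contrast_fixtures <- function() {
  panel <- htr2a_panel()
  enc <- function(rows) t(vapply(rows, encode_individual, integer(7),
                                 panel = panel))
  risk_rows <- list(
    c("CC", "CA", "CC", "TT", "GG", "CC", "Double"),
    c("CC", "AA", "CC", "TT", "AG", "CT", "Double"),
    c("CC", "AA", "CC", "CT", "AG", "CT", "Double"),
    c("CC", "CA", "CC", "TT", "AG", "CT", "Double"),
    c("CC", "AA", "CC", "CT", "GG", "CC", "Double"),
    c("CC", "CA", "CC", "CT", "AG", "CT", "Double"))
  prot_rows <- list(
    c("CC", "AA", "CC", "TT", "AG", "CT", "No"),
    c("CC", "AA", "CC", "CT", "AG", "CT", "No"),
    c("CC", "CA", "CC", "CT", "AG", "CT", "No"),
    c("CC", "CA", "CC", "TT", "AG", "CT", "No"),
    c("CT", "CA", "CC", "TT", "AG", "CT", "No"),
    c("CC", "CA", "CC", "TT", "AA", "TT", "No"),
    c("CC", "AA", "CC", "TT", "GG", "CT", "No"),
    c("CC", "AA", "CC", "TT", "AA", "TT", "No"))
  totals <- list(eira = c(N_h = 779L, N_s = 1500L),
                 narac = c(N_h = 866L, N_s = 711L))
  make <- function(states, n_h, n_s, cohort)
    gv_table_from_counts(states, n_h, n_s, panel,
                         N_h = totals[[cohort]]["N_h"],
                         N_s = totals[[cohort]]["N_s"])
  list(
    panel = panel,
    risk = list(
      eira = make(enc(risk_rows), c(1, 6, 6, 9, 9, 4),
                  c(16, 35, 35, 38, 47, 33), "eira"),
      narac = make(enc(risk_rows), c(3, 7, 2, 9, 3, 4),
                   c(15, 25, 17, 36, 19, 17), "narac")),
    protective = list(
      eira = make(enc(prot_rows), c(45, 40, 30, 57, 16, 25, 28, 11),
                  c(47, 38, 33, 41, 5, 22, 28, 9), "eira"),
      narac = make(enc(prot_rows), c(40, 34, 51, 65, 14, 42, 24, 21),
                   c(1, 1, 1, 1, 1, 3, 1, 1), "narac")),
    or_example = list(N_h = 779L, N_s = 1500L, n_h = 4L, n_s = 33L))
}
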