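#' Encode one individual's genotypes as a genetic vector
#'
#' @param labels Character vector of raw state labels, one per panel marker,
#'   in panel order.
#' @param panel The `marker_panel`.
#' @return Integer vector of state indices \eqn{\gamma \in \{1,2,3\}}.
#' @examples
#' encode_individual(c("CC", "CA", "CC", "TT", "GG", "CC", "Double"),
#'                   htr2a_panel())
#' @export
encode_individual <- function(labels, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  if (length(labels) != length(panel))
    stop("expected ", length(panel), " labels, got ", length(labels))
  g <- integer(length(panel))
  for (j in seq_along(panel)) {
    if (is.na(labels[j]))
      stop("missing label at marker '", panel[[j]]$name,
           "': incomplete individuals cannot be encoded")
    g[j] <- encode_genotype(panel[[j]], labels[j])
  }
  g
}

gv_key <- function(states) {
  if (is.matrix(states)) apply(states, 1L, paste, collapse = "-")
  else paste(states, collapse = "-")
}

gv_unkey <- function(keys) {
  if (length(keys) == 0L) return(matrix(integer(), 0L, 0L))
  do.call(rbind, lapply(strsplit(keys, "-", fixed = TRUE), as.integer))
}

# lexicographic row order of a state matrix
gv_order <- function(states) {
  if (nrow(states) == 0L) return(integer())
  do.call(order, as.data.frame(states))
}

new_gv_table <- function(states, n_h, n_s, panel, N_h, N_s) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  o <- gv_order(states)
  states <- states[o, , drop = FALSE]
  rownames(states) <- gv_key(states)
  colnames(states) <- panel_names(panel)
  structure(list(panel = panel, states = states,
                 n_h = as.integer(n_h[o]), n_s = as.integer(n_s[o]),
                 N_h = as.integer(N_h), N_s = as.integer(N_s)),
            class = "gv_table")
}

#' Group a cohort into genetic-vector groups
#'
#' Sorts all complete individuals into groups sharing the same ordered
#' genotype-state tuple and counts controls and cases per group. Incomplete
#' individuals (missing or unknown labels) are excluded with a message
#' before grouping.
#'
#' @param cohort A `cohort_genotypes`.
#' @param panel Optional panel; defaults to the cohort's own.
#' @return An object of class `gv_table`: the panel, a matrix of distinct
#'   state tuples in lexicographic order, per-group control/case counts
#'   `n_h`/`n_s`, and cohort totals `N_h`/`N_s` over retained individuals.
#' @seealso [gv_table_from_counts()] to build a table from pre-grouped counts.
#' @export
gv_table <- function(cohort, panel = cohort$panel) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  if (!identical(panel_names(panel), panel_names(cohort$panel)))
    stop("panel does not match the cohort's panel")
  cohort <- complete_genotypes(cohort)
  n <- length(cohort$id)
  if (n == 0L) stop("no individuals with complete genotypes")
  key <- gv_key(cohort$states)
  n_h <- rowsum(as.integer(cohort$phenotype == "control"), key)
  n_s <- rowsum(as.integer(cohort$phenotype == "case"), key)
  new_gv_table(gv_unkey(rownames(n_h)), n_h[, 1L], n_s[, 1L], panel,
               N_h = sum(cohort$phenotype == "control"),
               N_s = sum(cohort$phenotype == "case"))
}

#' Build a genetic-vector table from pre-grouped counts
#'
#' Published per-group count tables can be used directly as inputs: each row
#' gives a state tuple and its control/case counts. Cohort totals default to
#' the column sums but may be set larger when the rows are a subset of a
#' cohort (e.g. a selected contrast group, with totals from the full cohort).
#'
#' @param states Integer matrix (groups x markers) of state tuples, or a
#'   character vector of dash-joined keys like `"1-2-1-3-3-1-3"`.
#' @param n_h,n_s Integer vectors of per-group control and case counts.
#' @param panel The `marker_panel`.
#' @param N_h,N_s Cohort totals; default `sum(n_h)`, `sum(n_s)`.
#' @return A `gv_table`.
#' @export
gv_table_from_counts <- function(states, n_h, n_s, panel,
                                 N_h = sum(n_h), N_s = sum(n_s)) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.character(states)) states <- gv_unkey(states)
  states <- as.matrix(states)
  if (ncol(states) != length(panel))
    stop("state tuples must have one entry per panel marker")
  if (nrow(states) != length(n_h) || nrow(states) != length(n_s))
    stop("'n_h' and 'n_s' must have one entry per state tuple")
  if (!all(states %in% 1:3)) stop("state indices must be in 1..3")
  if (any(n_h < 0) || any(n_s < 0) || any(n_h + n_s < 1))
    stop("each group needs n_h >= 0, n_s >= 0 and n_h + n_s >= 1")
  if (anyDuplicated(gv_key(states)))
    stop("duplicate state tuples; merge counts before construction")
  if (N_h < sum(n_h) || N_s < sum(n_s))
    stop("cohort totals cannot be smaller than the per-group sums")
  new_gv_table(states, n_h, n_s, panel, N_h, N_s)
}

#' @export
print.gv_table <- function(x, n = 6L, ...) {
  cat(sprintf(
    "Genetic-vector table: %d GV groups, %d markers; N_h = %d, N_s = %d\n",
    nrow(x$states), ncol(x$states), x$N_h, x$N_s))
  df <- as.data.frame(x)
  print(utils::head(df, n), row.names = FALSE)
  if (nrow(df) > n) cat("  ... ", nrow(df) - n, " more group(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gv_table <- function(x, ...) {
  data.frame(gv = rownames(x$states), n_h = x$n_h, n_s = x$n_s,
             stringsAsFactors = FALSE)
}

#' Index matrix of a genetic vector
#'
#' The 3 x N binary matrix with entry \eqn{(\gamma, i) = 1} exactly when the
#' vector takes state \eqn{\gamma} at marker \eqn{i}; each column holds a
#' single 1. Weighted averages of index matrices over groups of individuals
#' are the genotype-frequency maps of [frequency_map()].
#'
#' @param gv Integer vector of states in 1..3 (or a dash-joined key string).
#' @param panel Optional `marker_panel` used to label the columns.
#' @return A 3 x N 0/1 matrix with rows `gamma1..gamma3`.
#' @examples
#' index_matrix(c(2, 1, 3))
#' @export
index_matrix <- function(gv, panel = NULL) {
  if (is.character(gv)) gv <- as.integer(strsplit(gv, "-", fixed = TRUE)[[1L]])
  gv <- as.integer(gv)
  if (length(gv) == 0L || !all(gv %in% 1:3))
    stop("a genetic vector is a nonempty tuple of states in 1..3")
  m <- matrix(0L, 3L, length(gv),
              dimnames = list(paste0("gamma", 1:3),
                              if (is.null(panel)) NULL else panel_names(panel)))
  m[cbind(gv, seq_along(gv))] <- 1L
  m
}

group_total <- function(table, group = c("h", "s")) {
  group <- match.arg(group)
  if (group == "h") table$n_h else table$n_s
}

#' Genotype-frequency map of a group
#'
#' The weighted average of the index matrices of all genetic vectors in the
#' table, with weights proportional to the group's per-vector counts: entry
#' \eqn{(\gamma, i)} is the fraction of the group's individuals carrying
#' state \eqn{\gamma} at marker \eqn{i}. Every column sums to 1. When the
#' table holds a selected subset of a cohort this is exactly the weighted
#' contrast average used for genotype-content comparison.
#'
#' @param table A `gv_table`.
#' @param group `"h"` (controls) or `"s"` (cases).
#' @return A 3 x N numeric matrix with columns summing to 1.
#' @export
frequency_map <- function(table, group = c("h", "s")) {
  stopifnot(inherits(table, "gv_table"))
  w <- group_total(table, group)
  tot <- sum(w)
  if (tot == 0L)
    stop("group '", match.arg(group), "' is empty in this table")
  f <- matrix(0, 3L, ncol(table$states),
              dimnames = list(paste0("gamma", 1:3), colnames(table$states)))
  for (g in 1:3)
    f[g, ] <- colSums((table$states == g) * w) / tot
  f
}

#' Rate of a pair of genotype states
#'
#' Fraction of a group's individuals whose genetic vector carries state
#' `a[2]` at marker `a[1]` and state `b[2]` at marker `b[1]`; the diagonal
#' case `a == b` reduces to the corresponding [frequency_map()] entry.
#'
#' @param table A `gv_table`.
#' @param a,b Length-2 integer vectors `(marker index, state)`. The two
#'   markers must differ unless the pairs are identical.
#' @param group `"h"` or `"s"`.
#' @return A rate in \[0, 1\].
#' @export
pair_rate <- function(table, a, b, group = c("h", "s")) {
  stopifnot(inherits(table, "gv_table"), length(a) == 2L, length(b) == 2L)
  if (a[1L] == b[1L] && a[2L] != b[2L])
    stop("two different states at the same marker never co-occur; ",
         "use distinct markers or an identical pair")
  w <- group_total(table, group)
  tot <- sum(w)
  if (tot == 0L) stop("group '", match.arg(group), "' is empty in this table")
  hit <- table$states[, a[1L]] == a[2L] & table$states[, b[1L]] == b[2L]
  sum(w[hit]) / tot
}

#' Crop genetic vectors to a subset of markers
#'
#' Projects every vector onto the kept marker positions and merges groups
#' whose projections coincide by summing their counts. Control and case
#' totals are conserved. Cropping is how one asks which markers actually
#' drive a group-level association: markers whose removal does not change
#' the contrast are uninformative.
#'
#' @param table A `gv_table`.
#' @param keep Marker positions (integer) or names to keep; must be
#'   nonempty.
#' @return A `gv_table` on the reduced panel.
#' @export
crop <- function(table, keep) {
  stopifnot(inherits(table, "gv_table"))
  if (is.character(keep)) {
    miss <- setdiff(keep, colnames(table$states))
    if (length(miss) > 0L)
      stop("unknown marker(s): ", paste(miss, collapse = ", "))
    keep <- match(keep, colnames(table$states))
  }
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L)
    stop("'keep' must retain at least one marker: a genetic vector of ",
         "length zero is undefined")
  if (any(keep < 1L) || any(keep > ncol(table$states)))
    stop("'keep' positions outside the panel")
  sub <- table$states[, keep, drop = FALSE]
  key <- gv_key(sub)
  n_h <- rowsum(table$n_h, key)
  n_s <- rowsum(table$n_s, key)
  new_gv_table(gv_unkey(rownames(n_h)), n_h[, 1L], n_s[, 1L],
               table$panel[keep], table$N_h, table$N_s)
}

#' Common genetic-vector basis of several tables
#'
#' The union of the genetic-vector sets of the given tables, in
#' lexicographic order, together with per-table membership masks. Vectors
#' present in every table are the "common" basis on which cohorts can be
#' compared; a table whose vector set misses some union members is simply
#' extended by those vectors with zero counts.
#'
#' @param tables A list of `gv_table`s sharing one panel.
#' @return A list with `states` (union matrix), `keys`, and `membership`
#'   (logical matrix, union x tables), plus `common` (logical: present in
#'   all tables).
#' @export
common_basis <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ok <- vapply(tables, inherits, logical(1), "gv_table")
  if (!all(ok)) stop("all elements must be gv_table objects")
  pn <- lapply(tables, function(t) panel_names(t$panel))
  if (!all(vapply(pn, identical, logical(1), pn[[1L]])))
    stop("tables are on different marker panels")
  keys <- lapply(tables, function(t) rownames(t$states))
  uni <- sort(unique(unlist(keys)))
  states <- gv_unkey(uni)
  o <- gv_order(states)
  states <- states[o, , drop = FALSE]
  uni <- uni[o]
  rownames(states) <- uni
  colnames(states) <- pn[[1L]]
  membership <- vapply(keys, function(k) uni %in% k, logical(length(uni)))
  membership <- matrix(membership, nrow = length(uni),
                       dimnames = list(uni, names(tables)))
  list(states = states, keys = uni, membership = membership,
       common = rowSums(membership) == length(tables))
}

#' Write a genetic-vector table to TSV (+ JSON sidecar)
#'
#' The TSV holds `gv<TAB>n_h<TAB>n_s` with dash-joined state tuples; the
#' sidecar `<path>.json` records the panel and the cohort totals so the
#' table round-trips exactly.
#'
#' @param table A `gv_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gv_table <- function(table, path) {
  stopifnot(inherits(table, "gv_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(N_h = table$N_h, N_s = table$N_s,
               markers = lapply(unclass(table$panel), function(m)
                 list(name = m$name, kind = m$kind, states = m$states)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a genetic-vector table written by [write_gv_table()]
#'
#' @param path TSV path; `<path>.json` must exist alongside.
#' @return A `gv_table`.
#' @export
read_gv_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "integer",
                                                "integer"))
  side <- jsonlite::fromJSON(paste0(path, ".json"), simplifyDataFrame = FALSE)
  panel <- marker_panel(lapply(side$markers, function(m)
    marker_def(m$name, unlist(m$states), kind = m$kind)))
  gv_table_from_counts(tab$gv, tab$n_h, tab$n_s, panel,
                       N_h = side$N_h, N_s = side$N_s)
}
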