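#' Define a three-state genetic marker
#'
#' A marker is either a biallelic SNP, whose three states are the
#' homozygous-reference, heterozygous and homozygous-alternate genotypes, or a
#' categorical variable with three ordered levels (for example the HLA-DRB1
#' shared-epitope allele count coded No/Single/Double). The position of a
#' label in `states` is the state index \eqn{\gamma \in \{1,2,3\}} used
#' throughout the package.
#'
#' For SNP markers heterozygote labels are matched irrespective of allele
#' order, so "CA" and "AC" denote the same state.
#'
#' @param name Marker name, e.g. the rs identifier. Must be unique in a panel.
#' @param states Character vector of exactly three distinct state labels, in
#'   the order that defines \eqn{\gamma = 1, 2, 3}.
#' @param kind `"snp"` or `"categorical"`.
#' @return An object of class `marker_def`.
#' @examples
#' marker_def("rs6311", c("CC", "CT", "TT"))
#' marker_def("SE", c("No", "Single", "Double"), kind = "categorical")
#' @export
marker_def <- function(name, states, kind = c("snp", "categorical")) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  states <- as.character(states)
  if (length(states) != 3L || anyNA(states) || !all(nzchar(states)))
    stop("marker '", name, "': 'states' must be three non-empty labels")
  key <- normalize_label(states, kind)
  if (anyDuplicated(key))
    stop("marker '", name, "': state labels are not distinct: ",
         paste(states, collapse = ", "))
  structure(list(name = name, kind = kind, states = states, key = key),
            class = "marker_def")
}

# canonical form used for matching: allele characters of a SNP genotype are
# sorted so "CA" == "AC"; categorical labels are matched verbatim
normalize_label <- function(labels, kind) {
  if (kind != "snp") return(labels)
  vapply(labels, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(sort(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.marker_def <- function(x, ...) {
  cat(sprintf("<marker %s (%s): %s>\n", x$name, x$kind,
              paste(x$states, collapse = "/")))
  invisible(x)
}

#' Assemble an ordered marker panel
#'
#' The panel fixes the marker order once; every genetic vector, index matrix
#' and group table built from it uses this order, and cohorts can only be
#' compared when they share it.
#'
#' @param ... `marker_def` objects, or a single list of them.
#' @return An object of class `marker_panel`.
#' @seealso [htr2a_panel()] for the built-in 7-marker example panel.
#' @export
marker_panel <- function(...) {
  markers <- list(...)
  if (length(markers) == 1L && !inherits(markers[[1L]], "marker_def"))
    markers <- markers[[1L]]
  if (length(markers) == 0L)
    stop("a panel needs at least one marker")
  ok <- vapply(markers, inherits, logical(1), "marker_def")
  if (!all(ok)) stop("all panel elements must be marker_def objects")
  nm <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate marker names in panel: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(markers) <- nm
  structure(markers, class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel with %d markers:\n", length(x)))
  for (m in x)
    cat(sprintf("  %-10s %-11s %s\n", m$name, m$kind,
                paste(m$states, collapse = "/")))
  invisible(x)
}

#' @export
`[.marker_panel` <- function(x, i) {
  marker_panel(unclass(x)[i])
}

panel_names <- function(panel) vapply(panel, `[[`, character(1), "name")

#' Read a marker panel from a YAML or JSON file
#'
#' The file holds a list of markers, each with fields `name`, `states`
#' (three labels in state order) and optionally `kind` (default `"snp"`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `marker_panel`.
#' @export
read_panel <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
  if (!is.null(cfg$markers)) cfg <- cfg$markers
  marker_panel(lapply(cfg, function(m) {
    marker_def(m$name, unlist(m$states), kind = m$kind %||% "snp")
  }))
}

#' Write a marker panel to YAML
#'
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  yaml::write_yaml(list(markers = lapply(unclass(panel), function(m)
    list(name = m$name, kind = m$kind, states = as.list(m$states)))), path)
  invisible(path)
}

#' The HTR2A + shared-epitope rheumatoid-arthritis panel
#'
#' The seven-marker panel used in published rheumatoid-arthritis cohort
#' analyses: six SNPs from the HTR2A locus followed by the HLA-DRB1
#' shared-epitope (SE) allele count as a categorical three-state marker.
#'
#' @return A `marker_panel` of length 7.
#' @examples
#' htr2a_panel()
#' @export
htr2a_panel <- function() {
  marker_panel(
    marker_def("rs6314",    c("CC", "CT", "TT")),
    marker_def("rs977003",  c("AA", "AC", "CC")),
    marker_def("rs1328674", c("CC", "CT", "TT")),
    marker_def("rs2070037", c("CC", "CT", "TT")),
    marker_def("rs6313",    c("AA", "AG", "GG")),
    marker_def("rs6311",    c("CC", "CT", "TT")),
    marker_def("SE",        c("No", "Single", "Double"), kind = "categorical")
  )
}

#' Encode a raw genotype label as a state index
#'
#' @param marker A `marker_def`.
#' @param label A raw state label; for SNP markers allele order is ignored.
#' @return The 1-based position of `label` in the marker's state labels
#'   (an integer in 1..3).
#' @examples
#' encode_genotype(marker_def("rs977003", c("AA", "AC", "CC")), "CA")
#' @export
encode_genotype <- function(marker, label) {
  stopifnot(inherits(marker, "marker_def"))
  g <- match(normalize_label(label, marker$kind), marker$key)
  if (anyNA(g) || length(label) != 1L)
    stop("marker '", marker$name, "': unknown genotype label '", label, "'")
  g
}

# vectorised encoding of one marker's label column; unknown labels -> NA
encode_column <- function(marker, labels) {
  match(normalize_label(labels, marker$kind), marker$key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
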