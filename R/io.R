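#' Construct a genotyped case-control cohort
#'
#' Holds per-individual raw genotype labels for every marker of a panel,
#' together with the case/control phenotype. Individuals with a missing or
#' unrecognized label at any marker are kept but flagged as incomplete;
#' genetic-vector construction uses complete individuals only, since a
#' genetic vector is defined only as a full product of marker states.
#'
#' @param id Character vector of individual identifiers.
#' @param labels Character matrix (individuals x markers) of raw state
#'   labels; `NA` marks a missing call. Column order must follow the panel.
#' @param phenotype Vector of phenotypes: `0`/`"control"`/`"h"` for controls,
#'   `1`/`"case"`/`"s"` for cases.
#' @param panel The `marker_panel` the labels refer to.
#' @return An object of class `cohort_genotypes` with elements `id`, `labels`,
#'   `phenotype` (factor control/case), `panel`, and `complete` (logical:
#'   all labels present and recognized).
#' @export
cohort_genotypes <- function(id, labels, phenotype, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  labels <- as.matrix(labels)
  n <- length(id)
  if (n != nrow(labels) && !(n == 0L && nrow(labels) == 0L))
    stop("'id' and 'labels' disagree on the number of individuals")
  if (ncol(labels) != length(panel) && n > 0L)
    stop("'labels' must have one column per panel marker")
  if (n == 0L) labels <- matrix(character(), 0L, length(panel))
  phenotype <- decode_phenotype(phenotype, n)
  colnames(labels) <- panel_names(panel)
  states <- encode_label_matrix(labels, panel)
  structure(list(id = as.character(id), labels = labels,
                 phenotype = phenotype, panel = panel,
                 states = states, complete = !apply(is.na(states), 1L, any)),
            class = "cohort_genotypes")
}

decode_phenotype <- function(pheno, n) {
  if (length(pheno) != n) stop("phenotype must be defined for every individual")
  map <- c("0" = "control", "1" = "case", control = "control", case = "case",
           h = "control", s = "case")
  v <- map[as.character(pheno)]
  if (anyNA(v) && n > 0L) {
    bad <- unique(as.character(pheno)[is.na(v)])
    stop("unknown phenotype code(s): ", paste(bad, collapse = ", "),
         " (use 0/control/h or 1/case/s)")
  }
  factor(unname(v), levels = c("control", "case"))
}

encode_label_matrix <- function(labels, panel) {
  states <- matrix(NA_integer_, nrow(labels), length(panel))
  for (j in seq_along(panel))
    states[, j] <- encode_column(panel[[j]], labels[, j])
  colnames(states) <- panel_names(panel)
  states
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  n <- length(x$id)
  cat(sprintf("Cohort of %d individuals (%d controls, %d cases) on %d markers\n",
              n, sum(x$phenotype == "control"), sum(x$phenotype == "case"),
              length(x$panel)))
  if (any(!x$complete))
    cat(sprintf("  %d individual(s) flagged incomplete (missing/unknown labels)\n",
                sum(!x$complete)))
  invisible(x)
}

#' Drop individuals with incomplete genotypes
#'
#' @param cohort A `cohort_genotypes`.
#' @param quiet Suppress the exclusion message.
#' @return The cohort restricted to individuals with a complete, recognized
#'   genotype at every panel marker.
#' @export
complete_genotypes <- function(cohort, quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  keep <- cohort$complete
  if (!quiet && any(!keep))
    message(sum(!keep), " of ", length(keep),
            " individuals excluded for missing/unknown genotype calls")
  subset_cohort(cohort, keep)
}

subset_cohort <- function(cohort, keep) {
  cohort$id <- cohort$id[keep]
  cohort$labels <- cohort$labels[keep, , drop = FALSE]
  cohort$states <- cohort$states[keep, , drop = FALSE]
  cohort$phenotype <- cohort$phenotype[keep]
  cohort$complete <- cohort$complete[keep]
  cohort
}

#' Read a tab-delimited genotype table
#'
#' Expected dialect: a header line `id<TAB>pheno<TAB><marker1>...<markerN>`,
#' phenotype coded 0 = control / 1 = case, and each marker column holding a
#' state label from that marker's alphabet or `NA`. Extra columns are
#' ignored; marker columns are matched by name, so column order need not
#' follow the panel. Rows with missing or unrecognized labels are retained
#' and flagged, never silently dropped.
#'
#' @param path Path to the TSV file.
#' @param panel The `marker_panel` naming the required columns.
#' @return A `cohort_genotypes`.
#' @export
read_genotype_table <- function(path, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("NA", ""), check.names = FALSE)
  need <- c("id", "pheno", panel_names(panel))
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("genotype table '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  cohort_genotypes(tab$id, as.matrix(tab[panel_names(panel)]),
                   tab$pheno, panel)
}

#' Write a cohort in the tab-delimited genotype dialect
#'
#' @param cohort A `cohort_genotypes`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  out <- data.frame(id = cohort$id,
                    pheno = as.integer(cohort$phenotype == "case"),
                    cohort$labels, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column phenotype file
#'
#' @param path TSV with header `id<TAB>pheno`, phenotype coded 0/1.
#' @return Named vector of phenotype codes, names = individual ids.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("id", "pheno") %in% names(tab)))
    stop("phenotype file '", path, "' must have columns 'id' and 'pheno'")
  structure(tab$pheno, names = tab$id)
}

#' Read panel genotypes from a VCF
#'
#' Panel SNPs are matched against the VCF `ID` column. Diploid `GT` fields
#' map onto state indices as 0/0 -> 1, 0/1 or 1/0 -> 2, 1/1 -> 3; the phasing
#' separator (`|` vs `/`) is ignored because the analysis is genotype-based,
#' not haplotype-based. `./.` becomes a missing call and flags the
#' individual. Phenotypes come from a separate two-column file (see
#' [read_phenotypes()]); samples without a phenotype entry are dropped with a
#' message.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param panel `marker_panel`; every marker must be present in the VCF by ID
#'   as a biallelic record.
#' @param pheno_path Path to the `id<TAB>pheno` phenotype file.
#' @return A `cohort_genotypes`.
#' @export
read_vcf <- function(path, panel, pheno_path) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf() requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(vcf)
  want <- panel_names(panel)
  miss <- setdiff(want, ids)
  if (length(miss) > 0L)
    stop("panel marker(s) absent from VCF: ", paste(miss, collapse = ", "))
  rows <- match(want, ids)
  alt <- vcfR::getALT(vcf)[rows]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) for panel marker(s): ",
         paste(want[multi], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")[rows, , drop = FALSE]
  samples <- colnames(gt)
  # dose = number of ALT alleles; anything not 0/0, 0/1, 1/0, 1/1 is missing
  dose <- matrix(NA_integer_, length(rows), length(samples))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[clean == "0/0"] <- 1L
  dose[clean == "0/1" | clean == "1/0"] <- 2L
  dose[clean == "1/1"] <- 3L
  labels <- matrix(NA_character_, length(samples), length(panel))
  for (j in seq_along(panel))
    labels[, j] <- panel[[j]]$states[dose[j, ]]
  pheno <- read_phenotypes(pheno_path)
  known <- samples %in% names(pheno)
  if (any(!known))
    message(sum(!known), " VCF sample(s) without phenotype entry dropped")
  cohort_genotypes(samples[known], labels[known, , drop = FALSE],
                   pheno[samples[known]], panel)
}
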