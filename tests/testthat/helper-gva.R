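# shared fixtures: a tiny 3-marker panel and cohort builders used across files

tiny_panel <- function() {
  marker_panel(
    marker_def("snpA", c("AA", "AC", "CC")),
    marker_def("snpB", c("GG", "GT", "TT")),
    marker_def("cat", c("No", "Single", "Double"), kind = "categorical")
  )
}

# build a cohort directly from integer state tuples
cohort_from_states <- function(states, pheno, panel = tiny_panel()) {
  states <- as.matrix(states)
  labels <- matrix(NA_character_, nrow(states), ncol(states))
  for (j in seq_len(ncol(states)))
    labels[, j] <- panel[[j]]$states[states[, j]]
  cohort_genotypes(sprintf("I%03d", seq_len(nrow(states))), labels,
                   pheno, panel)
}

# independent per-individual dictionary count (oracle for gv_table)
naive_gv_count <- function(cohort) {
  keys <- apply(cohort$states, 1L, paste, collapse = "-")
  keep <- cohort$complete
  keys <- keys[keep]
  pheno <- cohort$phenotype[keep]
  counts <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (is.null(counts[[k]])) counts[[k]] <- c(h = 0L, s = 0L)
    slot <- if (pheno[i] == "control") "h" else "s"
    counts[[k]][slot] <- counts[[k]][slot] + 1L
  }
  counts
}

# hypergeometric pmf from binomial coefficients (oracle for or_distribution)
choose_pmf <- function(N_h, N_s, n_t, k) {
  choose(N_s, k) * choose(N_h, n_t - k) / choose(N_h + N_s, n_t)
}

random_states <- function(n, m, seed = NULL) {
  matrix(sample(1:3, n * m, replace = TRUE), n, m)
}
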