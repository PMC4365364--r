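test_that("individuals encode to genetic vectors in panel order", {
  p <- htr2a_panel()
  expect_identical(
    encode_individual(c("CC", "CA", "CC", "TT", "GG", "CC", "Double"), p),
    c(1L, 2L, 1L, 3L, 3L, 1L, 3L))
  expect_identical(
    encode_individual(c("CC", "AA", "CC", "TT", "AG", "CT", "No"), p),
    c(1L, 1L, 1L, 3L, 2L, 2L, 1L))
  expect_identical(
    encode_individual(c("CC", "AA", "CC", "CC", "AA", "CC", "No"), p),
    rep(1L, 7L))
  expect_error(encode_individual(c("CC", NA, "CC", "TT", "GG", "CC", "No"), p),
               "missing label at marker 'rs977003'")
})

test_that("gv_table matches a naive per-individual dictionary count", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(20:100, 1)
    cohort <- cohort_from_states(random_states(n, 3),
                                 pheno = sample(0:1, n, replace = TRUE))
    if (all(cohort$phenotype == "control")) next
    tab <- gv_table(cohort)
    oracle <- naive_gv_count(cohort)
    expect_setequal(rownames(tab$states), names(oracle))
    for (k in names(oracle)) {
      i <- match(k, rownames(tab$states))
      expect_identical(tab$n_h[i], oracle[[k]][["h"]])
      expect_identical(tab$n_s[i], oracle[[k]][["s"]])
    }
    expect_identical(sum(tab$n_h) + sum(tab$n_s), n)
  }
})

test_that("degenerate groupings behave: one shared GV, all-distinct GVs", {
  one <- cohort_from_states(matrix(rep(c(1L, 2L, 3L), 5), 5, 3, byrow = TRUE),
                            pheno = c(0, 0, 1, 1, 1))
  tab <- gv_table(one)
  expect_identical(nrow(tab$states), 1L)
  expect_identical(c(tab$n_h, tab$n_s), c(2L, 3L))

  st <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(1, 2, 1), c(1, 3, 1))
  tab2 <- gv_table(cohort_from_states(st, pheno = c(0, 1, 1, 0, 1)))
  expect_identical(nrow(tab2$states), 5L)
  expect_true(all(tab2$n_h + tab2$n_s == 1L))
})

test_that("index matrices are single-entry column projectors", {
  im <- index_matrix(c(2, 1, 3))
  expect_identical(im, matrix(c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L), 3, 3,
                              dimnames = list(paste0("gamma", 1:3), NULL)))
  expect_identical(index_matrix(c(1, 1))["gamma1", ], c(1L, 1L))
  set.seed(1)
  for (len in c(1, 4, 9)) {
    gv <- sample(1:3, len, replace = TRUE)
    expect_true(all(colSums(index_matrix(gv)) == 1L))
  }
})

test_that("frequency maps equal count-weighted averages of index matrices", {
  set.seed(7)
  st <- random_states(12, 3)
  st <- st[!duplicated(apply(st, 1, paste, collapse = "-")), , drop = FALSE]
  n_h <- sample(0:9, nrow(st), replace = TRUE) + 1L
  n_s <- sample(0:9, nrow(st), replace = TRUE)
  n_s[1] <- n_s[1] + 1L
  tab <- gv_table_from_counts(st, n_h, n_s, tiny_panel())
  for (grp in c("h", "s")) {
    w <- if (grp == "h") n_h else n_s
    oracle <- Reduce(`+`, lapply(seq_len(nrow(st)), function(i)
      w[i] * index_matrix(st[i, ]))) / sum(w)
    got <- frequency_map(tab, grp)
    expect_equal(got, oracle, ignore_attr = TRUE)
    expect_equal(unname(colSums(got)), rep(1, 3))
  }
})

test_that("one-group and symmetric two-group frequency maps are exact", {
  tab1 <- gv_table_from_counts(rbind(c(2, 1, 3)), 4, 9, tiny_panel())
  expect_equal(frequency_map(tab1, "s"),
               index_matrix(c(2, 1, 3)), ignore_attr = TRUE)
  tab2 <- gv_table_from_counts(rbind(c(1, 2, 2), c(3, 2, 2)), c(5, 5),
                               c(2, 2), tiny_panel())
  expect_equal(unname(frequency_map(tab2, "h")[, 1]), c(0.5, 0, 0.5))
})

test_that("pair rates reduce to marginals on the diagonal and count exactly", {
  set.seed(3)
  st <- unique(random_states(30, 3))
  n_h <- sample(1:8, nrow(st), replace = TRUE)
  n_s <- sample(1:8, nrow(st), replace = TRUE)
  tab <- gv_table_from_counts(st, n_h, n_s, tiny_panel())
  expect_equal(pair_rate(tab, c(2, 1), c(2, 1), "s"),
               frequency_map(tab, "s")["gamma1", 2])
  # brute-force oracle over expanded individuals
  idx <- rep(seq_len(nrow(st)), n_h)
  expect_equal(pair_rate(tab, c(1, 2), c(3, 1), "h"),
               mean(st[idx, 1] == 2 & st[idx, 3] == 1))
  # single-GV table: rate is 1 for its own pairs, 0 otherwise
  tab1 <- gv_table_from_counts(rbind(c(2, 1, 3)), 3, 2, tiny_panel())
  expect_identical(pair_rate(tab1, c(1, 2), c(2, 1), "h"), 1)
  expect_identical(pair_rate(tab1, c(1, 1), c(2, 1), "h"), 0)
  expect_error(pair_rate(tab1, c(1, 1), c(1, 2), "h"), "same marker")
})

test_that("pair rates factorize for independently planted markers", {
  # counts built as an exact product of marginals: rate must equal the
  # product exactly, not just approximately
  marg1 <- c(2, 3, 5); marg2 <- c(1, 4, 5); marg3 <- c(10, 0, 0)
  st <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  n_s <- marg1[st[, 1]] * marg2[st[, 2]] * marg3[st[, 3]]
  keep <- n_s > 0
  tab <- gv_table_from_counts(st[keep, ], rep(1, sum(keep)), n_s[keep],
                              tiny_panel())
  r <- pair_rate(tab, c(1, 2), c(2, 3), "s")
  expect_equal(r, (marg1[2] / sum(marg1)) * (marg2[3] / sum(marg2)))
})

test_that("cropping merges projected groups and conserves counts", {
  fx <- contrast_fixtures()
  tab <- fx$risk$eira
  expect_identical(crop(tab, 1:7)$states, tab$states)

  dropped <- crop(tab, setdiff(1:7, 4))   # drop rs2070037
  expect_identical(nrow(dropped$states), 4L)
  i <- match("1-1-1-2-2-3", rownames(dropped$states))
  expect_identical(dropped$n_h[i], 12L)
  expect_identical(dropped$n_s[i], 70L)

  set.seed(5)
  st <- unique(random_states(40, 3))
  tab2 <- gv_table_from_counts(st, sample(1:5, nrow(st), TRUE),
                               sample(1:5, nrow(st), TRUE), tiny_panel())
  for (keep in list(c(1, 2), 2, c(2, 3), c(1, 3))) {
    cr <- crop(tab2, keep)
    expect_identical(sum(cr$n_h), sum(tab2$n_h))
    expect_identical(sum(cr$n_s), sum(tab2$n_s))
  }
  expect_error(crop(tab2, integer(0)), "at least one marker")
  expect_error(crop(tab2, "nope"), "unknown marker")
})

test_that("distinct vectors never merge without cropping; identical always do", {
  st <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 3, 3))
  cohort <- cohort_from_states(st, pheno = c(0, 1, 1))
  tab <- gv_table(cohort)
  expect_identical(nrow(tab$states), 2L)
  expect_error(gv_table_from_counts(st, c(1, 1, 1), c(1, 1, 1), tiny_panel()),
               "duplicate")
})

test_that("the common basis is the deterministic union with membership masks", {
  p <- tiny_panel()
  t1 <- gv_table_from_counts(rbind(c(1, 1, 1), c(2, 2, 2)), c(1, 1), c(1, 1), p)
  t2 <- gv_table_from_counts(rbind(c(3, 3, 3), c(1, 2, 3), c(2, 1, 2)),
                             c(1, 1, 1), c(1, 1, 1), p)
  expect_true(all(common_basis(list(t1, t1))$common))
  b <- common_basis(list(t1, t2))
  expect_identical(length(b$keys), 5L)
  expect_identical(sum(b$common), 0L)
  expect_identical(b$keys, sort(b$keys))

  # cohort-sized example: sets of 161 and 163 sharing 131 give a union of 193
  set.seed(9)
  pool <- unique(random_states(500, 6))[1:193, ]
  p5 <- marker_panel(lapply(1:6, function(i)
    marker_def(paste0("m", i), c("AA", "AC", "CC"))))
  shared <- pool[1:131, ]; only1 <- pool[132:161, ]; only2 <- pool[162:193, ]
  ta <- gv_table_from_counts(rbind(shared, only1), rep(1, 161), rep(1, 161), p5)
  tb <- gv_table_from_counts(rbind(shared, only2), rep(1, 163), rep(1, 163), p5)
  bb <- common_basis(list(ta, tb))
  expect_identical(length(bb$keys), 193L)
  expect_identical(sum(bb$common), 131L)
  expect_error(common_basis(list(t1, ta)), "different marker panels")
})

test_that("gv tables round-trip through the TSV + JSON serialization", {
  fx <- contrast_fixtures()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gv_table(fx$protective$narac, f)
  back <- read_gv_table(f)
  expect_identical(back$states, fx$protective$narac$states)
  expect_identical(back$n_h, fx$protective$narac$n_h)
  expect_identical(back$n_s, fx$protective$narac$n_s)
  expect_identical(back$N_h, fx$protective$narac$N_h)
  expect_identical(back$N_s, fx$protective$narac$N_s)
})
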