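make_pair_tables <- function(shared, only_a, only_b, panel = tiny_panel()) {
  mk <- function(st) gv_table_from_counts(st, rep(2L, nrow(st)),
                                          rep(3L, nrow(st)), panel)
  list(a = mk(rbind(shared, only_a)), b = mk(rbind(shared, only_b)))
}

test_that("cohort alignment recovers a planted overlap exactly", {
  set.seed(14)
  pool <- unique(random_states(60, 3))
  shared <- pool[1:5, ]; oa <- pool[6:8, ]; ob <- pool[9:12, ]
  tt <- make_pair_tables(shared, oa, ob)
  al <- align_cohorts(tt$a, tt$b)
  expect_setequal(al$common, apply(shared, 1, paste, collapse = "-"))
  expect_setequal(al$a_only, apply(oa, 1, paste, collapse = "-"))
  expect_setequal(al$b_only, apply(ob, 1, paste, collapse = "-"))
  expect_identical(al$counts["a_only", "n_h"], 6L)   # 3 GVs x 2 controls
  ident <- align_cohorts(tt$a, tt$a)
  expect_identical(length(ident$a_only), 0L)
  expect_identical(length(ident$common), nrow(tt$a$states))
})

test_that("effect-direction stratification is a true partition", {
  expect_identical(stratify_omega("g", 2.0, 3.0)$omega_11, "g")
  expect_identical(stratify_omega("g", 0.5, 2.0)$omega_21, "g")
  expect_identical(stratify_omega("g", 2.0, 0.5)$omega_12, "g")
  set.seed(17)
  keys <- sprintf("k%02d", 1:40)
  or_a <- exp(stats::rnorm(40)); or_b <- exp(stats::rnorm(40))
  om <- stratify_omega(keys, or_a, or_b)
  parts <- list(om$omega_11, om$omega_12, om$omega_21, om$omega_22)
  expect_identical(sort(unlist(parts)), sort(keys))
  expect_identical(sum(lengths(parts)), 40L)
  # planted signs are recovered
  expect_setequal(om$omega_11, keys[or_a > 1 & or_b > 1])
  expect_error(stratify_omega(keys, or_a[-1], or_b), "align")
  expect_error(stratify_omega("g", NA_real_, 1.2), "finite")
})

test_that("an odds ratio of exactly 1 falls on the protective side", {
  om <- stratify_omega(c("x", "y"), c(1.0, 2.0), c(2.0, 2.0))
  expect_identical(om$omega_21, "x")
  expect_identical(om$omega_11, "y")
  expect_identical(om$boundary, 1L)
})

test_that("consistency selection requires both cohorts to clear thresholds", {
  p <- tiny_panel()
  # one strong shared risk GV, one GV strong in cohort A only
  st <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  ta <- gv_table_from_counts(st, c(10, 10, 480), c(120, 110, 1270), p)
  tb1 <- gv_table_from_counts(st, c(10, 10, 480), c(120, 35, 1345), p)
  keys <- rownames(ta$states)
  sa <- gv_stats(ta); sb <- gv_stats(tb1)
  om <- stratify_omega(keys, sa$or[match(keys, sa$gv)],
                       sb$or[match(keys, sb$gv)])
  sel <- select_consistent(om, sa, sb)
  strong <- paste(c(1, 1, 1), collapse = "-")
  weak_b <- paste(c(2, 2, 2), collapse = "-")
  expect_true(strong %in% sel$risk)
  expect_false(weak_b %in% sel$risk)
  d <- sel$details
  expect_true(d$or_b[d$gv == weak_b] <= d$threshold_b[d$gv == weak_b])
  # empty risk class gives an empty risk set
  om0 <- stratify_omega(character(0), numeric(0), numeric(0))
  expect_identical(select_consistent(om0, sa, sb)$risk, character(0))
})

test_that("protective selection inverts odds ratios for reporting", {
  p <- tiny_panel()
  st <- rbind(c(1, 1, 1), c(2, 2, 2))
  ta <- gv_table_from_counts(st, c(120, 380), c(20, 980), p)
  sa <- gv_stats(ta)
  om <- stratify_omega(rownames(ta$states), sa$or, sa$or)
  sel <- select_consistent(om, sa, sa)
  d <- sel$details[sel$details$side == "protective", ]
  expect_equal(d$or_inv_a, 1 / d$or_a)
  expect_true(all(sel$protective %in% om$omega_22))
})

test_that("selection is monotone in alpha", {
  cfg <- sim_config(seed = 29, n_gv = 50,
                    planted_or = c(4, 3, 0.3, rep(1, 47)), N_h = 800, N_s = 900)
  pair <- generate_pair(cfg)
  ta <- gv_table(pair$a); tb <- gv_table(pair$b)
  picked <- lapply(c(0.2, 0.1, 0.05, 0.01), function(a) {
    fit <- gva(ta, tb, alpha = a)
    c(fit$selection$risk, fit$selection$protective)
  })
  for (i in 2:length(picked))
    expect_true(all(picked[[i]] %in% picked[[i - 1]]))
})

test_that("contrast averages are column-stochastic and reduce to the IM", {
  fx <- contrast_fixtures()
  one <- subset_gv_table(fx$risk$eira, rownames(fx$risk$eira$states)[3],
                         "subset")
  expect_equal(contrast_average(one, "s"),
               index_matrix(fx$risk$eira$states[3, ]), ignore_attr = TRUE)
  for (tab in list(fx$risk$eira, fx$protective$narac)) {
    cs <- contrast_average(tab, "s")
    ch <- contrast_average(tab, "h")
    expect_equal(unname(colSums(cs)), rep(1, 7), tolerance = 1e-12)
    expect_equal(unname(colSums(cs - ch)), rep(0, 7), tolerance = 1e-12)
  }
})

test_that("zero-GV profiles average the right subsets and flag consistency", {
  p <- tiny_panel()
  st <- rbind(c(1, 2, 1), c(1, 2, 3), c(2, 1, 2), c(3, 1, 1))
  # GV1+GV2 solely sick, GV3 solely healthy, GV4 mixed
  ta <- gv_table_from_counts(st, c(0, 0, 6, 5), c(4, 2, 0, 5), p)
  z <- zero_gv_matrices(ta)
  expect_identical(z$a$n_ss_gv, 2L)
  expect_identical(z$a$n_sh_gv, 1L)
  oracle_ss <- (4 * index_matrix(c(1, 2, 1)) + 2 * index_matrix(c(1, 2, 3))) / 6
  expect_equal(z$a$ss, oracle_ss, ignore_attr = TRUE)
  expect_equal(z$a$sh, index_matrix(c(2, 1, 2)), ignore_attr = TRUE)
  expect_equal(unname(colSums(z$a$diff)), rep(0, 3), tolerance = 1e-12)
  # the planted case-only GVs are rich in state 2 at marker 2 in both
  # cohorts: positive, consistent difference at that cell
  tb <- gv_table_from_counts(st, c(0, 1, 7, 6), c(3, 0, 0, 6), p)
  zz <- zero_gv_matrices(ta, tb)
  expect_gt(zz$a$diff["gamma2", 2], 0)
  expect_true(isTRUE(zz$consistent["gamma2", 2]))
  # single solely-sick GV reduces to its index matrix
  tc <- gv_table_from_counts(st[c(1, 3), ], c(0, 2), c(5, 1), p)
  expect_equal(zero_gv_matrices(tc)$a$ss, index_matrix(st[1, ]),
               ignore_attr = TRUE)
  expect_null(zero_gv_matrices(tc)$a$sh)
})

test_that("self-comparison places a planted risk GV in the risk set", {
  cfg <- sim_config(seed = 41, n_gv = 40, planted_or = c(6, rep(1, 39)),
                    base_weights = c(0.02, rep(0.98 / 39, 39)),
                    N_h = 900, N_s = 1200, perturb = 0)
  pair <- generate_pair(cfg)
  tab <- gv_table(pair$a)
  fit <- gva(tab, tab)
  planted <- pair$truth$keys[1]
  expect_true(planted %in% fit$omega$omega_11)
  expect_true(planted %in% fit$selection$risk)
})

test_that("the full pipeline is deterministic given the generator seed", {
  run <- function() {
    pair <- generate_pair(sim_config(seed = 52, n_gv = 45,
                                     planted_or = c(3, rep(1, 44))))
    fit <- gva(pair$a, pair$b)
    fit$call <- NULL
    fit
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("published contrast tables reproduce the reported selection", {
  fx <- contrast_fixtures()
  comb <- function(r, p) gv_table_from_counts(
    rbind(r$states, p$states), c(r$n_h, p$n_h), c(r$n_s, p$n_s), r$panel,
    N_h = r$N_h, N_s = r$N_s)
  fit <- gva(comb(fx$risk$eira, fx$protective$eira),
             comb(fx$risk$narac, fx$protective$narac),
             totals = "raw", names = c("EIRA", "NARAC"))
  expect_setequal(fit$selection$risk, rownames(fx$risk$eira$states))
  expect_setequal(fit$selection$protective,
                  rownames(fx$protective$eira$states))
  # genotype-content profiles as published: risk cases vs protective controls
  expect_equal(fit$contrast$a$risk_case["gamma1", "rs977003"], 0.5735,
               tolerance = 1e-4)
  expect_equal(fit$contrast$a$protective_control["gamma1", "rs977003"],
               0.4921, tolerance = 1e-4)
  expect_equal(fit$contrast$b$risk_case["gamma1", "rs977003"], 0.4729,
               tolerance = 1e-4)
  expect_equal(fit$contrast$b$protective_control["gamma1", "rs977003"],
               0.4089, tolerance = 1e-4)
  # the worked threshold example is one of the risk groups
  d <- fit$selection$details
  ex <- d[d$or_a > 4.35 & d$or_a < 4.36, ]
  expect_equal(ex$threshold_a, 1.9, tolerance = 1e-3)
})
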