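test_that("spearman handles monotone, reversed and tied data", {
  expect_equal(spearman(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman(c(1, 2, 3), c(2, 4, 6))$p, 0)
  expect_equal(spearman(c(1, 2, 3), c(6, 4, 2))$rho, -1)

  # ties: midrank formula against direct Pearson-on-ranks and an exhaustive
  # 4!-permutation p-value
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  sp <- spearman(x, y, exact = TRUE)
  rx <- rank(x); ry <- rank(y)
  rho_direct <- stats::cor(rx, ry)
  expect_equal(sp$rho, rho_direct, tolerance = 1e-12)
  allp <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 4), ]
  rhos <- apply(allp, 1, function(pp) stats::cor(rx, ry[unlist(pp)]))
  expect_equal(sp$p, mean(abs(rhos) >= abs(rho_direct) - 1e-12))

  # agreement with the stats oracle on untied data
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(15); b <- rnorm(15)
    ref <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    got <- spearman(a, b)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }

  # invariance under strictly monotone transforms; antisymmetry
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman(exp(a), b)$rho, spearman(a, b)$rho)
  expect_equal(spearman(a, -b)$rho, -spearman(a, b)$rho)

  # degenerate input flagged; short input rejected
  expect_true(spearman(rep(1, 5), 1:5)$flagged)
  expect_error(spearman(1:2, 1:2), "at least 3")

  # pairwise deletion of missing values
  sp2 <- spearman(c(1, 2, NA, 4, 5), c(2, 4, 6, NA, 10))
  expect_equal(sp2$n, 3)
  expect_equal(sp2$rho, 1)
})

test_that("correlation screen flags pairs by the stated rule", {
  g <- make_coupled_cohort(40, planted_rho = 1, seed = 5)
  res <- correlation_screen(g$cohort, "feature", "parameter")
  overall <- res[res$subgroup == "overall", ]
  expect_equal(overall$rho, 1)
  expect_true(overall$strong)

  # null at n = 1000: nothing flagged at the 0.7 threshold
  for (s in 1:5) {
    gn <- make_coupled_cohort(1000, planted_rho = 0, seed = s)
    rn <- correlation_screen(gn$cohort, "feature", "parameter")
    expect_false(any(rn$strong))
  }

  # negative planted correlation: flagged under abs mode, not signed mode
  gneg <- make_coupled_cohort(60, planted_rho = -0.97, seed = 2)
  r_abs <- correlation_screen(gneg$cohort, "feature", "parameter",
                              mode = "abs")
  r_sgn <- correlation_screen(gneg$cohort, "feature", "parameter",
                              mode = "signed")
  expect_true(any(r_abs$strong[r_abs$subgroup == "overall"]))
  expect_false(any(r_sgn$strong[r_sgn$subgroup == "overall"]))

  # subgroup-specific effect at the published subgroup sizes (15 / 22)
  hits <- vapply(1:60, function(s) {
    g <- make_coupled_cohort(37, planted_rho = c(saccular = 0.9, fusiform = 0),
                             n_saccular = 15, seed = s)
    r <- correlation_screen(g$cohort, "feature", "parameter",
                            subgroup_col = "subgroup")
    r$strong[r$subgroup == "saccular"] && !r$strong[r$subgroup == "fusiform"]
  }, logical(1))
  expect_gte(mean(hits), 0.75)

  # small subgroup skipped with a message
  g2 <- make_coupled_cohort(10, 0.5, n_saccular = 2, seed = 1)
  expect_message(
    r2 <- correlation_screen(g2$cohort, "feature", "parameter",
                             subgroup_col = "subgroup"),
    "skipped")
  expect_false("saccular" %in% r2$subgroup)

  # deterministic ordering and row-permutation invariance
  g3 <- make_coupled_cohort(30, 0.4, seed = 3)
  r3 <- correlation_screen(g3$cohort, "feature", "parameter")
  shuffled <- g3$cohort[sample(nrow(g3$cohort)), ]
  r3s <- correlation_screen(shuffled, "feature", "parameter")
  expect_equal(r3, r3s, ignore_attr = TRUE)

  expect_error(correlation_screen(g3$cohort, "feature", "nope"),
               "missing columns")
})

test_that("cohort screening summary reproduces printed-style arithmetic", {
  # published screening log: 44 identified, 4 flow artifact + 2 image quality
  # + 1 CFD failure excluded, 22 fusiform / 15 saccular included, 16 cavernous
  log <- data.frame(
    case_id = sprintf("c%02d", 1:44),
    included = c(rep(TRUE, 37), rep(FALSE, 7)),
    exclusion_reason = c(rep(NA, 37), rep("flow artifact", 4),
                         rep("poor image quality", 2), rep("CFD failure", 1)),
    type = c(rep("fusiform", 22), rep("saccular", 15), rep(NA, 7)),
    location = c(rep("cavernous ICA", 16), rep("other", 21), rep(NA, 7)),
    stringsAsFactors = FALSE)
  s <- cohort_screening_summary(log)
  expect_equal(s$n_identified, 44)
  expect_equal(s$n_included, 37)
  expect_equal(s$types$pct[s$types$level == "fusiform"], 59.5)
  expect_equal(s$types$pct[s$types$level == "saccular"], 40.5)
  expect_equal(s$locations$pct[s$locations$level == "cavernous ICA"], 43.2)
  expect_equal(s$exclusions$pct[s$exclusions$level == "flow artifact"], 9.1)
  expect_equal(s$exclusions$pct[s$exclusions$level == "poor image quality"],
               4.5)

  # no exclusions, single type -> 100.0%
  log2 <- data.frame(case_id = c("a", "b"), included = TRUE,
                     exclusion_reason = NA, type = "saccular")
  s2 <- cohort_screening_summary(log2)
  expect_equal(s2$types$pct, 100)
  expect_null(s2$exclusions)

  expect_error(cohort_screening_summary(data.frame()), "empty")
  # included case without a type label
  log3 <- log2; log3$type[1] <- NA
  expect_error(cohort_screening_summary(log3), "type")
})

test_that("round_half_up rounds .05 upward at one decimal", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(59.45, 1), 59.5)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(2.349, 2), 2.35)
})
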