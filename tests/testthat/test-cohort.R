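test_that("Ward merges match brute-force objective minimization up to n = 8", {
  for (s in 1:4) {
    set.seed(s)
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    cl <- cluster_ward(x, k = 2)
    oracle <- ward_brute_force(x)
    expect_identical(hclust_merge_sets(cl$hclust), oracle$merges)
    ## ward.D2 heights are sqrt(2 * objective increase)
    expect_equal(cl$hclust$height^2 / 2, oracle$costs, tolerance = 1e-10)
  }
})

test_that("automatic k selection separates well-split clouds and supports edge cases", {
  set.seed(2)
  x <- rbind(matrix(rnorm(20 * 2, 0, 0.5), 20, 2),
             matrix(rnorm(15 * 2, 20, 0.5), 15, 2))
  cl <- cluster_ward(x, "auto")
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:35])), 1)
  expect_true(cl$labels[1] != cl$labels[35])
  expect_true(all(cl$diagnostics$k == 2:6))
  ## k = n gives singletons; k > n errors
  cl_n <- cluster_ward(x[1:5, ], k = 5)
  expect_equal(sort(unname(cl_n$labels)), 1:5)
  expect_error(cluster_ward(x[1:5, ], k = 6), "must be in")
  ## the dendrogram serializes to Newick
  expect_match(cl$newick, "^\\(.*;$")
})

test_that("Welch cluster tests: identical groups, symmetry, and power on planted shifts", {
  x <- data.frame(f = c(1, 2, 3, 1, 2, 3))
  lab <- c(1, 1, 1, 2, 2, 2)
  tt <- cluster_feature_tests(x, lab)
  expect_equal(tt$p, 1)
  expect_equal(tt$t, 0)
  set.seed(3)
  y <- data.frame(f = rnorm(31))
  lab2 <- rep(1:2, c(15, 16))
  t1 <- cluster_feature_tests(y, lab2)
  t2 <- cluster_feature_tests(y, 3 - lab2)
  expect_equal(abs(t1$t), abs(t2$t))
  expect_equal(t1$p, t2$p)
  ## a +3 pooled-sd shift at n = 15/16 is detected at p < 0.001 almost surely
  hits <- 0L
  set.seed(11)
  for (r in 1:100) {
    z <- c(rnorm(15), rnorm(16, 3))
    p <- cluster_feature_tests(data.frame(f = z), lab2)$p
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits, 95)
  ## degenerate variance is reported missing, not invented
  const <- data.frame(f = rep(5, 6))
  expect_warning(td <- cluster_feature_tests(const, lab), "degenerate")
  expect_true(is.na(td$p))
  expect_error(cluster_feature_tests(x, c(1, 1, 1, 1, 1, 2)), "at least 2")
})

test_that("Mann-Whitney subgroup tests follow the exact-enumeration oracle", {
  mw <- mitoifc:::mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_true(mw$exact)
  expect_equal(mw$p, mann_whitney_enumerate(c(1, 2, 3), c(4, 5, 6)))
  set.seed(4)
  for (r in 1:5) {
    a <- rnorm(4)   # continuous draws: tie-free, so the exact path applies
    b <- rnorm(5)
    expect_equal(mitoifc:::mann_whitney(a, b)$p, mann_whitney_enumerate(a, b),
                 tolerance = 1e-10)
  }
  ## subgroup orchestration: n < 3 subgroups are reported untested
  x <- data.frame(membrane_potential_pct = c(80, 82, 78, 120, 118, 95))
  st <- c("A", "A", "A", "B", "B", "C")
  ref <- data.frame(membrane_potential_pct = c(98, 101, 99, 102, 100, 97))
  out <- subgroup_vs_reference(x, st, ref)
  expect_setequal(out$tests$subtype, "A")
  expect_setequal(out$untested, c("B", "C"))
  expect_lt(out$tests$p, 0.05)
  ## a subgroup drawn identically to the reference is not significant
  same <- subgroup_vs_reference(
    data.frame(membrane_potential_pct = c(98, 101, 99)), c("A", "A", "A"),
    data.frame(membrane_potential_pct = c(98, 101, 99)))
  expect_equal(same$tests$p, 1)
})

test_that("Spearman phenotype correlations match the rank formula and handle NA", {
  x <- data.frame(feat = c(10, 20, 30, 40))
  clin <- data.frame(phen = c("No", "No", "Yes", "Yes"))
  out <- phenotype_correlation(x, clin)
  expect_equal(unname(out$rho["feat", "phen"]),
               spearman_rank_formula(x$feat, c(0, 0, 1, 1)))
  expect_equal(unname(out$rho["feat", "phen"]), 0.8944, tolerance = 1e-4)
  ## permutation null: mean rho near 0, always within [-1, 1]
  set.seed(9)
  rhos <- replicate(300, {
    cl <- data.frame(phen = sample(c("Yes", "No"), 12, TRUE))
    unname(phenotype_correlation(data.frame(f = rnorm(12)), cl)$rho)
  })
  rhos <- rhos[!is.na(rhos)]
  expect_lt(abs(mean(rhos)), 0.1)
  expect_true(all(rhos >= -1 & rhos <= 1))
  ## NA rows are excluded pairwise; constant phenotypes report missing rho
  clin2 <- data.frame(phen = c("Yes", "NA", "Yes", "No"))
  out2 <- phenotype_correlation(x, clin2)
  expect_equal(unname(out2$n["feat", "phen"]), 3)
  out3 <- phenotype_correlation(x, data.frame(phen = c("Yes", "Yes", "Yes",
                                                       "NA")))
  expect_true(is.na(out3$rho["feat", "phen"]))
})

test_that("Fisher cluster-phenotype test equals hypergeometric enumeration", {
  lab <- rep(1:2, each = 5)
  ph <- c(rep("Yes", 5), rep("No", 5))
  out <- cluster_phenotype_fisher(lab, ph)
  expect_equal(out$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(out$p, 0.00794, tolerance = 1e-3)
  ## identical rows: no association
  out2 <- cluster_phenotype_fisher(rep(1:2, each = 6),
                                   rep(c("Yes", "Yes", "No"), 4))
  expect_equal(out2$p, 1)
  ## random tables with margins <= 10 against full enumeration
  set.seed(7)
  for (r in 1:10) {
    tab <- matrix(sample(0:5, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    lab_r <- rep(1:2, rowSums(tab))
    ph_r <- c(rep(c(1, 0), tab[1, ]), rep(c(1, 0), tab[2, ]))
    got <- cluster_phenotype_fisher(lab_r, ph_r)
    expect_equal(got$p, fisher_enumerate(got$table), tolerance = 1e-9)
    expect_true(got$p >= 0 && got$p <= 1)
  }
  ## empty margins: p = 1, odds ratio undefined; NA phenotypes excluded
  out3 <- cluster_phenotype_fisher(rep(1:2, each = 3), rep("Yes", 6))
  expect_equal(out3$p, 1)
  expect_true(is.na(out3$odds_ratio))
  out4 <- cluster_phenotype_fisher(c(lab, 1, 2), c(ph, "NA", NA))
  expect_equal(sum(out4$table), 10)
})

test_that("statistical results are invariant to donor ordering", {
  d <- cohort_design(n_patients = 12, n_controls = 3,
                     cluster_assignment = rep(1:2, each = 6), seed = 5)
  v <- donor_vectors(generate_cohort_table(d))
  m <- cohort_matrix(v)
  lab <- attr(m, "cluster")
  set.seed(1)
  perm <- sample(nrow(m))
  t1 <- cluster_feature_tests(m, lab)
  t2 <- cluster_feature_tests(m[perm, ], lab[perm])
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  f1 <- cluster_phenotype_fisher(lab, ifelse(lab == 2, "Yes", "No"))
  f2 <- cluster_phenotype_fisher(lab[perm], ifelse(lab[perm] == 2, "Yes",
                                                   "No"))
  expect_equal(f1$p, f2$p)
})

test_that("cohort matrix applies the missing-data policy", {
  d <- cohort_design(n_patients = 10, n_controls = 3, seed = 6)
  v <- donor_vectors(generate_cohort_table(d))
  v$ros_pct[v$donor_id == "P03"] <- NA
  m_drop <- cohort_matrix(v, "drop")
  expect_false("P03" %in% rownames(m_drop))
  m_imp <- cohort_matrix(v, "impute")
  expect_true("P03" %in% rownames(m_imp))
  expect_false(anyNA(m_imp))
})
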