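test_that("simulation configs validate their constraints", {
  expect_error(sim_config(h2_epi = 0.6, h2_direct = 0.6), "sum")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(rare_fraction = 1.2), "rare_fraction")
  expect_error(sim_config(rare_range = c(0.02, 0.1)), "disjoint")
})

test_that("cohort simulation is seeded, respects MAF ranges, and matches binomial sampling", {
  cfg <- sim_config(n = 2000, causal_per_gene = 40, m_direct = 40, m_neutral = 20,
                    rare_fraction = 0, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$H1, c2$H1)
  expect_identical(c1$references, c2$references)
  # rare_fraction = 0: every contributing site is common
  contrib <- c1$sites$role %in% c("re_causal", "direct")
  expect_true(all(c1$sites$maf[contrib] >= 0.05))
  # empirical MAFs within 3 binomial SEs of the drawn MAFs for >= 99% of sites
  emp <- colSums(c1$H1 + c1$H2) / (2 * cfg$n)
  se <- sqrt(c1$sites$maf * (1 - c1$sites$maf) / (2 * cfg$n))
  ok <- abs(emp - c1$sites$maf) <= 3 * se
  expect_gte(mean(ok), 0.99)
  # dosage identity and polymorphism
  expect_true(all(dosage_matrix(c1) == c1$H1 + c1$H2))
  expect_true(all(emp > 0 & emp < 1))
})

test_that("rare_fraction draws the requested number of rare contributing sites", {
  cfg <- sim_config(n = 3000, causal_per_gene = 40, m_direct = 40, m_neutral = 20,
                    rare_fraction = 0.5, seed = 7)
  cohort <- simulate_cohort(cfg)
  for (r in c("re_causal", "direct")) {
    idx <- cohort$sites$role == r
    expect_equal(sum(cohort$sites$maf[idx] < 0.01), round(0.5 * sum(idx)))
  }
  # neutral sites stay common
  expect_true(all(cohort$sites$maf[cohort$sites$role == "neutral"] >= 0.05))
})

test_that("genotype normalization is exact and matches a two-pass oracle", {
  cfg <- sim_config(n = 500, causal_per_gene = 20, m_direct = 20, m_neutral = 10, seed = 3)
  cohort <- simulate_cohort(cfg)
  X <- normalize_genotypes(cohort)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_lt(max(abs(colMeans(X^2) - 1)), 1e-12)
  # brute-force two-pass oracle on one column
  d <- dosage_matrix(cohort)[, 7]
  mu <- sum(d) / length(d)
  sd2 <- sqrt(sum((d - mu)^2) / length(d))
  expect_equal(X[, 7], (d - mu) / sd2, ignore_attr = TRUE)
  d0 <- matrix(1L, 10, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(normalize_genotypes(d0), "monomorphic")
})

test_that("annotations give one gene per block, RE-contained causal sets, and a calibrated binding matrix", {
  cfg <- sim_config(n = 200, n_blocks = 2, causal_per_gene = 100, m_direct = 30,
                    m_neutral = 10, n_tf = 10, tf_hit_prob = 0.3, seed = 12)
  cohort <- simulate_cohort(cfg)
  ann <- build_annotations(cohort)
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(length(ann$causal_sets), 2L)
  # every causal site lies inside a regulatory element of its block
  for (g in seq_len(2)) {
    idx <- ann$causal_sets[[g]]
    expect_equal(length(idx), 100L)
    res <- ann$re_intervals[ann$re_intervals$block == ann$genes$block[g], ]
    inside <- vapply(cohort$sites$pos0[idx], function(p)
      any(p >= res$start & p < res$end), TRUE)
    expect_true(all(inside))
  }
  # binding density: 10 TFs x 200 causal sites at 0.3 -> total within 3 SD of 600
  total <- sum(ann$B)
  expect_lt(abs(total - 600), 3 * sqrt(2000 * 0.3 * 0.7) + 1)
  expect_true(all(rowSums(ann$B) >= 1))
  expect_true(all(ann$B %in% c(0L, 1L)))
})

test_that("liability components hit their target variances exactly and are near-independent", {
  cfg <- sim_config(n = 4000, h2_epi = 0.5, h2_direct = 0.3, h2_inter = 0.1,
                    f_inter = 0.5, seed = 21)
  sim <- regpheno(cfg)
  comp <- sim$components
  pv <- function(x) mean((x - mean(x))^2)
  expect_lt(abs(pv(comp$y_epi) - 0.5), 1e-10)
  expect_lt(abs(pv(comp$y_direct) - 0.3), 1e-10)
  expect_lt(abs(pv(comp$y_inter) - 0.1), 1e-10)
  expect_lt(abs(mean(comp$y_epi)), 1e-10)
  # environmental variance is sampled, not rescaled: within 5% of target
  expect_lt(abs(pv(comp$y_env) - 0.1) / 0.1, 0.05)
  # disjoint SNP sets: epigenetic and direct components nearly uncorrelated
  expect_lt(abs(cor(comp$y_epi, comp$y_direct)), 0.05)
  # total liability variance near 1
  expect_lt(abs(pv(comp$liability) - 1), 0.05)
})

test_that("zero-proportion components vanish and degenerate draws error", {
  cfg <- sim_config(n = 500, h2_epi = 0, h2_direct = 0.5, h2_inter = 0, seed = 2)
  sim <- regpheno(cfg)
  expect_equal(sim$components$y_epi, rep(0, 500))
  expect_equal(sim$components$y_inter, rep(0, 500))
  # constant genotype matrix: raw component constant, target variance > 0
  cohort <- simulate_cohort(cfg)
  ann <- build_annotations(cohort, cfg)
  draws <- draw_effects(ann, cohort, cfg)
  Xconst <- matrix(0, cfg$n, nrow(cohort$sites))
  expect_error(compute_liability(Xconst, ann, draws, cfg), "degenerate")
})

test_that("threshold phenotypes are exact and bernoulli intercepts calibrate the prevalence", {
  cfg <- sim_config(n = 4000, seed = 31)
  sim <- regpheno(cfg)
  expect_equal(sum(sim$labels), 2000L)
  # alpha0 is the implied cut: alpha0 + eta >= 0 iff case
  expect_true(all((sim$alpha0 + sim$components$liability >= 0) == (sim$labels == 1)))

  cfgb <- sim_config(n = 4000, phenotype_mode = "bernoulli", prevalence = 0.3, seed = 31)
  simb <- regpheno(cfgb)
  expect_lt(abs(mean(simb$mu) - 0.3), 1e-8)
  # all liabilities equal: alpha0 = logit(lambda) in closed form
  comp <- structure(list(liability = rep(0, 100)), class = "liability_components")
  ph <- assign_phenotypes(comp, sim_config(n = 100, phenotype_mode = "bernoulli",
                                           prevalence = 0.3, seed = 1))
  expect_equal(ph$alpha0, qlogis(0.3), tolerance = 1e-8)
})

test_that("bernoulli case fractions stay within binomial bounds across seeds", {
  hits <- 0L
  for (s in 1:30) {
    cfg <- sim_config(n = 1000, causal_per_gene = 20, m_direct = 20, m_neutral = 5,
                      phenotype_mode = "bernoulli", seed = s)
    sim <- regpheno(cfg)
    tol <- 3 * sqrt(0.5 * 0.5 / 1000)
    hits <- hits + (abs(mean(sim$labels) - 0.5) <= tol)
  }
  expect_gte(hits, 27L)  # >= 95% of runs within 3 SD, allowing sampling slack
})

test_that("the rare-variant dial lowers per-SNP association power", {
  med_chisq <- function(rare_fraction) {
    vals <- numeric(20)
    for (r in seq_len(20)) {
      cfg <- sim_config(n = 1500, causal_per_gene = 10, m_direct = 40, m_neutral = 10,
                        h2_epi = 0, h2_direct = 1, h2_inter = 0,
                        rare_fraction = rare_fraction, f_inter = 0,
                        seed = 1000 + r)
      sim <- regpheno(cfg)
      stats <- assoc_scan(dosage_matrix(sim$cohort), sim$labels, sim$cohort$sites)
      vals[r] <- median(stats$chisq[sim$cohort$sites$role == "direct"])
    }
    mean(vals)
  }
  expect_lt(med_chisq(1), med_chisq(0))
})

test_that("replicate runner derives distinct deterministic seeds", {
  fun <- function(cfg, setting, rep) data.frame(seed_used = cfg$seed)
  settings <- list(a = sim_config(n = 50), b = sim_config(n = 50))
  t1 <- run_replicates(settings, 20, fun, master_seed = 5)
  t2 <- run_replicates(settings, 20, fun, master_seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40L)
  expect_equal(sum(t1$setting == "a"), 20L)
  expect_equal(anyDuplicated(t1$seed), 0L)
})
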