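make_cases <- function(variant, muts = NULL, panel = NULL) {
  n <- length(variant)
  df <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                   diagnosis = "MDS-RS", sf3b1_variant = variant,
                   stringsAsFactors = FALSE)
  df$comutations <- muts %||% replicate(
    n, data.frame(gene = character(), vaf = numeric()), simplify = FALSE)
  df$panel_genes <- panel %||% replicate(n, myeloid_panel_genes(),
                                         simplify = FALSE)
  df
}
mut <- function(...) {
  g <- c(character(), ...)
  data.frame(gene = g, vaf = rep(0.4, length(g)), stringsAsFactors = FALSE)
}

test_that("partition percentages reproduce the hand-checked fractions", {
  cases <- printed_partition_cohort()
  pd <- partition_distribution(cases,
                               variants_of_interest = c("K666N", "E592K",
                                                        "E622D", "K666R"))
  tab <- pd$table
  pick <- function(v, d) tab[tab$variant == v & tab$diagnosis == d, ]
  expect_equal(pick("K666N", "MDS-RS")$percent_printed, "2.1")   # 28/1327
  expect_equal(pick("K666N", "AML")$percent_printed, "25.8")     # 103/399
  expect_equal(pick("E592K", "MDS-RS")$percent_printed, "0.08")  # 1/1327
  expect_equal(pick("E592K", "AML")$percent_printed, "2.5")      # 10/399
  expect_equal(pick("E622D", "MDS-RS")$percent_printed, "6.9")   # 92/1327
  expect_equal(pick("E622D", "AML")$percent_printed, "0.5")      # 2/399
  expect_equal(pick("K666R", "MDS-SLD/MLD")$percent_printed, "1.2")  # 3/242
  expect_equal(pick("E592K", "MDS-RS")$count, 1)
  expect_equal(pick("E592K", "MDS-RS")$total, 1327)
  # the E592K enrichment away from MDS-RS is exact-test significant
  tst <- pd$tests
  p <- tst$p_value[tst$variant == "E592K" & tst$diagnosis_a == "AML" &
                     tst$diagnosis_b == "MDS-RS"]
  expect_lt(p, 1e-4)
})

test_that("partitioning over an absent diagnosis is flagged undefined", {
  cases <- make_cases(c("K700E", "E592K"))
  pd <- partition_distribution(cases, variants_of_interest = "E592K",
                               diagnoses = c("MDS-RS", "AML"))
  aml <- pd$table[pd$table$diagnosis == "AML", ]
  expect_true(aml$undefined)
  expect_true(is.na(aml$percent))
})

test_that("Fisher exact test matches the enumeration oracle", {
  # balanced table carries no information
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # zero margin is degenerate by convention
  z <- fisher_exact_two_sided(matrix(c(0, 0, 7, 3), 2, byrow = TRUE))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_error(fisher_exact_two_sided(matrix(1:6, 2)), "2x2")
  # exhaustive check over all tables with margins <= 12
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_exact_two_sided(tab)$p_value
    expect_equal(got, oracle_fisher_p(tab), tolerance = 1e-12)
    # the test is invariant to transposition
    expect_equal(got, fisher_exact_two_sided(t(tab))$p_value,
                 tolerance = 1e-12)
  }
  # odds-ratio conventions
  ft <- fisher_exact_two_sided(matrix(c(8, 2, 3, 7), 2, byrow = TRUE))
  expect_equal(ft$odds_ratio, (8 * 7) / (2 * 3))
  ft0 <- fisher_exact_two_sided(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))
  expect_false(is.na(ft0$odds_ratio_cc))
  expect_equal(ft0$odds_ratio_cc, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("comutation frequencies use panel-aware denominators", {
  # 35 sequenced E592K cases, one DNMT3A mutation -> 1/35 = 2.9%
  muts_a <- replicate(35, mut(), simplify = FALSE)
  muts_a[[7]] <- mut("DNMT3A")
  a <- make_cases(rep("E592K", 35), muts = muts_a)
  muts_b <- replicate(40, mut(), simplify = FALSE)
  muts_b[1:8] <- replicate(8, mut("DNMT3A"), simplify = FALSE)
  b <- make_cases(rep("K700E", 40), muts = muts_b)
  cases <- rbind(a, b)
  cl <- comutation_landscape(cases,
                             function(r) r$sf3b1_variant == "E592K",
                             function(r) r$sf3b1_variant == "K700E",
                             genes = c("DNMT3A", "TET2"),
                             cohort_names = c("e592k", "hotspot"))
  dn <- cl[cl$gene == "DNMT3A", ]
  expect_equal(dn$n_e592k, 35)
  expect_equal(dn$mut_e592k, 1)
  expect_equal(format_percent(dn$freq_e592k), "2.9")
  # a gene mutated nowhere: frequencies 0, uninformative p
  te <- cl[cl$gene == "TET2", ]
  expect_equal(te$freq_e592k, 0)
  expect_equal(te$freq_hotspot, 0)
  expect_equal(te$p_value, 1)
  expect_true(all(cl$q_value >= cl$p_value - 1e-12))
  # a case whose panel lacks the gene leaves that gene's denominator
  panel <- replicate(75, myeloid_panel_genes(), simplify = FALSE)
  panel[[1]] <- setdiff(myeloid_panel_genes(), "DNMT3A")
  cases2 <- cases
  cases2$panel_genes <- panel
  cl2 <- comutation_landscape(cases2,
                              function(r) r$sf3b1_variant == "E592K",
                              function(r) r$sf3b1_variant == "K700E",
                              genes = "DNMT3A")
  expect_equal(cl2$n_a, 34)
  # empty cohorts are an error, not an empty result
  expect_error(comutation_landscape(cases, function(r) FALSE,
                                    function(r) TRUE, genes = "DNMT3A"),
               "empty cohort")
})

test_that("a strongly enriched gene earns the smallest q-value", {
  genes <- c("ASXL1", "DNMT3A", "TET2", "RUNX1", "STAG2", "EZH2")
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 60
    draw <- function(p_target) replicate(n, {
      m <- genes[c(stats::runif(1) < p_target,
                   stats::runif(length(genes) - 1) < 0.15)]
      mut(m)
    }, simplify = FALSE)
    cases <- rbind(make_cases(rep("E592K", n), muts = draw(0.6)),
                   make_cases(rep("K700E", n), muts = draw(0.08)))
    cl <- comutation_landscape(cases,
                               function(r) r$sf3b1_variant == "E592K",
                               function(r) r$sf3b1_variant == "K700E",
                               genes = genes)
    cl$gene[which.min(cl$q_value)] == "ASXL1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ring-sideroblast eligibility thresholds are strict", {
  e <- apply_rs_criterion(8, sf3b1_mutated = TRUE)
  expect_true(e$eligible_mutated_pathway)
  expect_false(e$eligible_unmutated_pathway)
  # exactly at the cutoffs: not eligible
  e5 <- apply_rs_criterion(5, sf3b1_mutated = TRUE)
  expect_false(e5$eligible_mutated_pathway)
  e15 <- apply_rs_criterion(15, sf3b1_mutated = FALSE)
  expect_false(e15$eligible_unmutated_pathway)
  # without the mutation, 14% RS qualifies through neither pathway
  e14 <- apply_rs_criterion(14, sf3b1_mutated = FALSE)
  expect_false(e14$eligible_mutated_pathway)
  expect_false(e14$eligible_unmutated_pathway)
  expect_true(apply_rs_criterion(16, FALSE)$eligible_unmutated_pathway)
  # unknown RS stays unknown
  na <- apply_rs_criterion(NA, TRUE)
  expect_true(is.na(na$eligible_mutated_pathway))
  expect_true(is.na(na$eligible_unmutated_pathway))
})

test_that("RS summaries average only known values and track the generator", {
  cases <- make_cases(rep("K700E", 4))
  cases$rs_percent <- c(20, 40, 60, NA)
  s <- summarize_rs(cases, function(r) TRUE)
  expect_equal(s$mean_rs, 40)
  expect_equal(s$n, 3L)
  none <- summarize_rs(cases, function(r) FALSE)
  expect_false(none$defined)
  expect_true(is.na(none$mean_rs))
  # simulated canonical-hotspot cases sit near the configured mean of 37%
  sim <- simulate_cohort(cohort_sim_config(n_cases = 500, seed = 13))
  hs <- summarize_rs(sim, function(r) r$sf3b1_exon %in% 14:16)
  expect_gt(hs$n, 100)
  expect_lt(abs(hs$mean_rs - 37), 2)
})

test_that("clinical comparisons match the exact permutation oracle", {
  cases <- data.frame(group = rep(c("a", "b"), each = 3),
                      platelets = c(1, 2, 3, 101, 102, 103))
  pa <- function(r) r$group == "a"; pb <- function(r) r$group == "b"
  cc <- compare_clinical(cases, pa, pb, "platelets")
  expect_equal(cc$p_value, oracle_ranksum_p(c(1, 2, 3), c(101, 102, 103)))
  expect_equal(cc$p_value, 0.1)
  expect_equal(cc$median_a, 2)
  expect_equal(cc$median_b, 102)
  # further random untied small samples against the oracle
  set.seed(31)
  for (rep in 1:5) {
    x <- sample(1:1000, 5); y <- sample(2000:3000, 6)
    cs <- data.frame(group = rep(c("a", "b"), c(5, 6)), v = c(x, y))
    got <- compare_clinical(cs, pa, pb, "v")$p_value
    expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
  # all-tied data is degenerate, not an error
  flat <- data.frame(group = rep(c("a", "b"), each = 3), v = 7)
  d <- compare_clinical(flat, pa, pb, "v")
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  tiny <- data.frame(group = c("a", "b", "b"), v = 1:3)
  expect_error(compare_clinical(tiny, pa, pb, "v"), "at least two")
})

test_that("the rank test detects a two-standard-deviation shift", {
  set.seed(77)
  rejected <- vapply(1:100, function(i) {
    cs <- data.frame(group = rep(c("a", "b"), each = 50),
                     v = c(rnorm(50, 0, 1), rnorm(50, 2, 1)))
    compare_clinical(cs, function(r) r$group == "a",
                     function(r) r$group == "b", "v")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("Kaplan-Meier estimates follow the product-limit formula", {
  k <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(k$surv[k$time == 2], 0.5)
  expect_equal(k$median, 2)
  # everyone censored: the curve never drops, median undefined
  flat <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_length(flat$time, 0)
  expect_true(is.na(flat$median))
  # random censored samples against the hand oracle
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    t <- sample(1:6, n, replace = TRUE)
    e <- stats::runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    got <- km_estimate(t, e)
    want <- oracle_km(t, e)
    expect_equal(got$time, want$time)
    expect_equal(got$surv, want$surv, tolerance = 1e-12)
  }
  # without censoring the curve is the empirical survivor function
  t <- c(2, 5, 5, 9, 11)
  k2 <- km_estimate(t, rep(TRUE, 5))
  for (i in seq_along(k2$time))
    expect_equal(k2$surv[i], mean(t > k2$time[i]))
  expect_error(km_estimate(numeric(), logical()), "empty")
})

test_that("log-rank statistics match the O-E oracle", {
  # identical groups: no evidence
  t <- c(1, 3, 4, 7); e <- c(TRUE, TRUE, FALSE, TRUE)
  lr0 <- logrank_test(t, e, t, e)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # no events anywhere: undefined, flagged
  nd <- logrank_test(c(1, 2), c(FALSE, FALSE), c(3, 4), c(FALSE, FALSE))
  expect_false(nd$defined)
  expect_true(is.na(nd$p_value))
  set.seed(19)
  for (rep in 1:10) {
    na <- sample(4:8, 1); nb <- sample(4:8, 1)
    ta <- sample(1:9, na, TRUE); tb <- sample(1:9, nb, TRUE)
    ea <- stats::runif(na) < 0.8; eb <- stats::runif(nb) < 0.8
    if (!any(ea) && !any(eb)) ea[1] <- TRUE
    got <- logrank_test(ta, ea, tb, eb)
    expect_equal(got$chisq, oracle_logrank_chisq(ta, ea, tb, eb),
                 tolerance = 1e-9)
  }
})

test_that("simulated survival separates E592K from canonical hotspots", {
  sim <- simulate_cohort(cohort_sim_config(n_cases = 3000, seed = 4))
  e <- sim[sim$sf3b1_variant == "E592K", ]
  h <- sim[sim$sf3b1_exon %in% 14:16, ]
  ke <- km_estimate(e$os_time, e$os_event)
  kh <- km_estimate(h$os_time, h$os_event)
  expect_lt(ke$median, kh$median)
  lr <- logrank_test(e$os_time, e$os_event, h$os_time, h$os_event)
  expect_lt(lr$p_value, 0.01)
})
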