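psi_mat <- function(m, samples = colnames(m)) {
  colnames(m) <- samples
  structure(list(psi = m), class = "psi_matrix")
}

test_that("delta PSI is the signed difference of group means", {
  m <- rbind(
    j1 = c(0.1, 0.1, 0.5, 0.5, 0.1, 0.1),   # +0.4 in MUT
    j2 = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),   # identical -> exactly 0
    j3 = c(0.3, NA, 0.7, 0.6, NA, NA)       # MUT2 has 1 informative sample
  )
  colnames(m) <- c("w1", "w2", "m1", "m2", "x1", "x2")
  gmap <- c(w1 = "WT", w2 = "WT", m1 = "MUT", m2 = "MUT", x1 = "MUT2", x2 = "MUT2")
  d <- delta_psi(psi_mat(m), gmap, "WT", quant_config(min_samples_per_group = 2))
  expect_equal(d$delta_MUT[d$junction == "j1"], 0.4)
  expect_equal(d$score[d$junction == "j1"], 0.4)
  expect_identical(d$delta_MUT[d$junction == "j2"], 0)
  # insufficient informative samples -> indeterminate NA, not zero
  expect_true(is.na(d$delta_MUT[d$junction == "j3"]))
  expect_true(is.na(d$delta_MUT2[d$junction == "j3"]))
  expect_true(d$indeterminate[d$junction == "j3"])
  expect_error(delta_psi(psi_mat(m), gmap[-1], "WT"), "genotype missing")
  expect_error(delta_psi(psi_mat(m), gmap, "ABSENT"), "reference genotype")
})

test_that("swapping the groups negates every delta exactly", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(8 * 6), nrow = 8,
                dimnames = list(paste0("j", 1:8), paste0("s", 1:6)))
    m[sample(length(m), 6)] <- NA
    g1 <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "B", s5 = "B", s6 = "B")
    d_ab <- delta_psi(psi_mat(m), g1, "A")
    d_ba <- delta_psi(psi_mat(m), g1, "B")
    expect_equal(d_ab$delta_B, -d_ba$delta_A)
  }
})

test_that("ranking is by score with a deterministic coordinate tie-break", {
  res <- data.frame(
    junction = c("chr2:100-200:+", "chr1:100-200:+", "chr1:100-150:+",
                 "chr1:90-210:+"),
    score = c(0.3, 0.3, 0.3, 0.5), stringsAsFactors = FALSE)
  r <- rank_events(res)
  expect_equal(r$junction,
               c("chr1:90-210:+", "chr1:100-150:+", "chr1:100-200:+",
                 "chr2:100-200:+"))
  expect_equal(nrow(rank_events(res, top_k = 2)), 2)
  expect_error(rank_events(res, top_k = 0), "top_k")
  # random instances match a full-sort oracle
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    res <- data.frame(
      junction = sprintf("chr%d:%d-%d:+", sample(1:3, n, TRUE),
                         st <- sample(100:999, n), st + sample(50:200, n)),
      score = round(runif(n), 2), stringsAsFactors = FALSE)
    res <- res[!duplicated(res$junction), ]
    got <- rank_events(res, top_k = 10)$junction
    co <- do.call(rbind, strsplit(gsub(":\\+$", "", res$junction), "[:-]"))
    want <- res$junction[order(-res$score, co[, 1], as.integer(co[, 2]),
                               as.integer(co[, 3]))][1:10]
    expect_identical(got, want)
  }
})

test_that("event classes follow the shared-anchor definitions", {
  ann <- one_intron_annotation("+")
  # canonical 1001-2000, cryptic acceptor 20 nt into the intron
  cl <- classify_event("chr1", 1001L, 1980L, "+", ann)
  expect_equal(cl$event_class, "alternative 3' acceptor")
  expect_equal(cl$canonical_partner, jid("chr1", 1001, 2000, "+"))
  expect_equal(cl$inserted_or_deleted_nt, 20L)
  expect_true(cl$frame_shift)
  # shared acceptor, shifted donor
  cl5 <- classify_event("chr1", 980L, 2000L, "+", ann)
  expect_equal(cl5$event_class, "alternative 5' donor")
  expect_equal(cl5$inserted_or_deleted_nt, -21L)
  # identical to canonical: a non-event
  expect_equal(classify_event("chr1", 1001L, 2000L, "+", ann)$event_class,
               "degenerate")
  # junction strictly inside the intron: retention proxy
  expect_equal(classify_event("chr1", 1200L, 1400L, "+", ann)$event_class,
               "intron retention proxy")
  # unanchored: other
  expect_equal(classify_event("chr1", 50L, 700L, "+", ann)$event_class,
               "other")
})

test_that("exon skipping removes exactly the skipped exon length", {
  ann <- example_annotation()  # G1 exons 101-220 / 301-420 / 501-640
  cl <- classify_event("chrT", 221L, 500L, "+", ann)
  expect_equal(cl$event_class, "exon skip")
  expect_equal(cl$inserted_or_deleted_nt, -120L)
  expect_false(cl$frame_shift)  # 120 nt exon preserves frame
})

test_that("frame arithmetic agrees with translating the rebuilt transcript", {
  ann <- example_annotation()
  # +20 nt insertion (frameshift) vs +18 nt insertion (in frame)
  for (case in list(list(shift = 20L, frame_shift = TRUE),
                    list(shift = 18L, frame_shift = FALSE))) {
    cryptic <- c(221L, 300L - case$shift)
    cl <- classify_event("chrT", cryptic[1], cryptic[2], "+", ann)
    expect_equal(cl$inserted_or_deleted_nt %% 3L != 0L, case$frame_shift)
    p <- predict_ptc_nmd(ann, "G1.t1", cryptic)
    if (!case$frame_shift) {
      # in-frame insertion of C-rich intron sequence: no stop gained
      expect_true(is.na(p$ptc_position))
    } else {
      expect_false(is.na(p$ptc_position))
    }
  }
})

test_that("the NMD 50-nt last-junction rule is applied on both sides", {
  # frameshifting insertion at intron 1 of G1: the new stop lands in exon 2,
  # far upstream of the exon2/exon3 junction -> NMD predicted
  ann <- example_annotation()
  p <- predict_ptc_nmd(ann, "G1.t1", c(221L, 280L))
  expect_true(p$applicable)
  expect_false(is.na(p$ptc_position))
  expect_gt(p$dist_to_last_junction, 50)
  expect_true(p$nmd_predicted)
  # same frameshift at the last intron: the stop falls in the last exon
  p2 <- predict_ptc_nmd(ann, "G1.t1", c(421L, 480L))
  expect_false(is.na(p2$ptc_position))
  expect_lt(p2$dist_to_last_junction, 0)
  expect_false(p2$nmd_predicted)
  # threshold is strict: a PTC exactly 50 nt upstream does not trigger NMD
  expect_false(is.na(p$ptc_position) ||
                 predict_ptc_nmd(ann, "G1.t1", c(221L, 280L),
                                 nmd_rule_nt = p$dist_to_last_junction)$nmd_predicted)
  # event outside the CDS is not applicable
  out <- predict_ptc_nmd(ann, "G1.t1", c(581L, 620L))
  expect_false(out$applicable)
  expect_true(is.na(out$nmd_predicted))
})

test_that("specificity labels follow the present/absent thresholds", {
  res <- data.frame(
    junction = c("j1", "j2", "j3", "j4"),
    mean_WT = 0.05, n_WT = 4L,
    mean_E592K = c(0.35, 0.35, 0.06, 0.05),
    n_E592K = c(4L, 4L, 4L, 1L),
    delta_E592K = c(0.30, 0.30, 0.01, NA),
    mean_K700E = c(0.06, 0.35, 0.35, 0.35),
    n_K700E = 4L,
    delta_K700E = c(0.01, 0.30, 0.30, 0.30),
    score = c(0.30, 0.30, 0.30, 0.30),
    stringsAsFactors = FALSE)
  sp <- call_specificity(res)
  lab <- setNames(sp$calls$label, sp$calls$junction)
  expect_equal(unname(lab["j1"]), "E592K-specific")
  expect_equal(unname(lab["j2"]), "shared")
  expect_equal(unname(lab["j3"]), "K700E-specific")
  # insufficient informative samples -> indeterminate, not absent
  expect_equal(unname(lab["j4"]), "ambiguous")
  expect_equal(sp$jaccard$jaccard, 1 / 4)  # {j1,j2} vs {j2,j3,j4}
  expect_error(call_specificity(res, t_present = 0.05, t_absent = 0.05),
               "t_absent")
})

test_that("relabeling genotypes permutes specificity labels consistently", {
  set.seed(9)
  res <- data.frame(junction = paste0("j", 1:20),
                    mean_WT = 0.05, n_WT = 4L,
                    delta_A = round(runif(20, -0.1, 0.4), 2), n_A = 4L,
                    delta_B = round(runif(20, -0.1, 0.4), 2), n_B = 4L,
                    stringsAsFactors = FALSE)
  swapped <- res
  names(swapped)[names(swapped) == "delta_A"] <- "delta_tmp"
  names(swapped)[names(swapped) == "delta_B"] <- "delta_A"
  names(swapped)[names(swapped) == "delta_tmp"] <- "delta_B"
  a <- call_specificity(res)$calls
  b <- call_specificity(swapped)$calls
  relabel <- function(x) ifelse(x == "A-specific", "B-specific",
                                ifelse(x == "B-specific", "A-specific", x))
  expect_identical(relabel(a$label), b$label)
})

test_that("planted delta PSI is recovered under study-design conditions", {
  # WT 0.05 vs E592K 0.50 at depth 200, rho 0.01, 4 clones per genotype:
  # the mean estimated delta over repeated simulations stays within 0.10
  ann <- tiled_annotation(1)
  errs <- vapply(1:20, function(seed) {
    ev <- plant_alt_acceptor(ann, "SG01.t1", 1, 20,
                             psi = c(WT = 0.05, K700E = 0.05, E592K = 0.50))
    cfg <- splice_sim_config(planted_events = list(ev), seed = seed)
    sim <- simulate_junction_counts(ann, cfg)
    g <- build_anchor_groups(sim$junctions, ann)
    psi <- compute_psi(g, sim$junctions)
    gmap <- setNames(sim$sample_info$genotype, sim$sample_info$sample_id)
    d <- delta_psi(psi, gmap, "WT")
    cj <- jid("chrS", ev$cryptic[1], ev$cryptic[2], "+")
    d$delta_E592K[d$junction == cj] - 0.45
  }, numeric(1))
  expect_true(all(abs(errs) < 0.10))
})

test_that("no-signal simulations stay below the false-call budget", {
  # all genotypes at the same PSI: 'present' calls at t_present = 0.10
  # should be rare (<= 5% of events on average)
  ann <- tiled_annotation(10)
  introns <- annotated_introns(ann)
  n_events <- 20
  calls <- vapply(1:10, function(seed) {
    evs <- lapply(seq_len(n_events), function(k)
      plant_alt_acceptor(ann, introns$transcript_id[k],
                         introns$intron_index[k], 20,
                         psi = c(WT = 0.1, K700E = 0.1, E592K = 0.1)))
    cfg <- splice_sim_config(planted_events = evs, seed = 1000 + seed)
    sim <- simulate_junction_counts(ann, cfg)
    g <- build_anchor_groups(sim$junctions, ann)
    psi <- compute_psi(g, sim$junctions)
    gmap <- setNames(sim$sample_info$genotype, sim$sample_info$sample_id)
    d <- delta_psi(psi, gmap, "WT")
    sp <- call_specificity(d)
    st <- as.matrix(sp$calls[, c("status_K700E", "status_E592K")])
    sum(st == "present") / (2 * nrow(st))
  }, numeric(1))
  expect_lte(mean(calls), 0.05)
})
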