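# Seeded generators standing in for restricted sequencing and registry data:
# genotype-dependent junction-count tables with planted hotspot-specific
# cryptic events, and clinical cohorts with variant-dependent diagnosis,
# co-mutation and survival structure.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Splice-simulation configuration
#'
#' Defaults mirror the experimental design emulated here: three genotypes
#' (wild type and the K700E and E592K SF3B1 hotspots), four independently
#' derived clones per genotype, a mean split-read depth of 200 per anchor,
#' and mild clone-to-clone overdispersion.
#'
#' @param genotypes genotype labels; the first is the reference
#' @param n_samples_per_genotype clones per genotype
#' @param depth_per_anchor mean total split-read count at an anchor
#' @param dispersion beta-binomial overdispersion rho in [0, 1)
#' @param planted_events list of planted events, e.g. from
#'   [plant_alt_acceptor()]; each is a list with event_id, chrom, strand,
#'   canonical = c(start, end), cryptic = c(start, end), and psi = named
#'   vector of per-genotype cryptic PSI
#' @param baseline_psi wild-type/default cryptic PSI used for genotypes not
#'   named in an event's psi vector (small but nonzero so filter and ranking
#'   edge cases are exercised)
#' @param seed integer seed
#' @return list of class `splice_sim_config`
#' @export
splice_sim_config <- function(genotypes = c("WT", "K700E", "E592K"),
                              n_samples_per_genotype = 4L,
                              depth_per_anchor = 200,
                              dispersion = 0.01,
                              planted_events = list(),
                              baseline_psi = 0.02,
                              seed = 1L) {
  stopifnot(n_samples_per_genotype >= 1, depth_per_anchor > 0,
            dispersion >= 0, dispersion < 1,
            baseline_psi >= 0, baseline_psi <= 0.05)
  for (ev in planted_events) {
    if (any(ev$psi < 0 | ev$psi > 1))
      stop("planted PSI outside [0,1] in event ", ev$event_id)
  }
  structure(list(genotypes = genotypes,
                 n_samples_per_genotype = as.integer(n_samples_per_genotype),
                 depth_per_anchor = depth_per_anchor,
                 dispersion = dispersion,
                 planted_events = planted_events,
                 baseline_psi = baseline_psi,
                 seed = as.integer(seed)),
            class = "splice_sim_config")
}

#' Plant a cryptic alternative 3' acceptor event
#'
#' Builds a planted-event description whose cryptic junction shares the
#' donor of an annotated intron while its acceptor is displaced into the
#' intron by `shift` nucleotides (the signature event class of SF3B1 hotspot
#' mutations).
#'
#' @param annotation a [toy_annotation()]
#' @param transcript_id transcript owning the intron
#' @param intron_index which intron (5' to 3')
#' @param shift nucleotides the acceptor moves into the intron (> 0)
#' @param psi named vector genotype -> cryptic PSI
#' @param event_id label; default derived from the coordinates
#' @return a planted-event list for [splice_sim_config()]
#' @export
plant_alt_acceptor <- function(annotation, transcript_id, intron_index, shift,
                               psi, event_id = NULL) {
  introns <- annotated_introns(annotation)
  it <- introns[introns$transcript_id == transcript_id &
                  introns$intron_index == intron_index, , drop = FALSE]
  if (nrow(it) != 1) stop("intron not found: ", transcript_id, " #", intron_index)
  stopifnot(shift > 0, shift < it$intron_end - it$intron_start)
  if (it$strand == "+") {
    cryptic <- c(it$intron_start, it$intron_end - shift)
  } else {
    cryptic <- c(it$intron_start + shift, it$intron_end)
  }
  list(event_id = event_id %||%
         sprintf("%s.i%d.a3ss%+d", transcript_id, intron_index, shift),
       chrom = it$chrom, strand = it$strand,
       canonical = c(it$intron_start, it$intron_end),
       cryptic = as.integer(cryptic),
       psi = psi)
}

# beta-binomial split: n trials, mean p, overdispersion rho
rbetabinom <- function(k, n, p, rho) {
  if (rho == 0 || p <= 0 || p >= 1) return(stats::rbinom(k, n, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  stats::rbinom(k, n, stats::rbeta(k, a, b))
}

#' Simulate genotype-dependent junction count tables
#'
#' For each planted event, each sample draws a Poisson total around
#' `depth_per_anchor` at the shared anchor and splits it between the
#' canonical and cryptic junctions by a beta-binomial draw whose mean is the
#' genotype's planted PSI. Annotated introns not involved in any planted
#' event receive fully canonical counts at the same depth. Output is a pure
#' function of the configuration (seeded).
#'
#' @param annotation a [toy_annotation()]
#' @param config a [splice_sim_config()]
#' @return list of class `splice_sim`: `junctions` (long junction-record
#'   data.frame across samples), `sample_info` (sample_id, genotype),
#'   `truth` (event_id, junction, genotype, true_psi), `annotation`, `config`
#' @export
simulate_junction_counts <- function(annotation, config) {
  stopifnot(inherits(config, "splice_sim_config"))
  if (config$depth_per_anchor <= 0) stop("non-positive depth")
  introns <- annotated_introns(annotation)
  ann_key <- paste(introns$chrom, introns$intron_start, introns$intron_end)
  for (ev in config$planted_events) {
    shares <- any(
      introns$chrom == ev$chrom &
        (anchor_pos(ev$cryptic[1], ev$cryptic[2], ev$strand, "donor") == introns$donor |
           anchor_pos(ev$cryptic[1], ev$cryptic[2], ev$strand, "acceptor") == introns$acceptor))
    if (!shares)
      stop("planted event ", ev$event_id,
           " shares no donor/acceptor with an annotated junction")
  }
  samples <- data.frame(
    sample_id = sprintf("%s_c%d",
                        rep(config$genotypes, each = config$n_samples_per_genotype),
                        rep(seq_len(config$n_samples_per_genotype),
                            times = length(config$genotypes))),
    genotype = rep(config$genotypes, each = config$n_samples_per_genotype),
    stringsAsFactors = FALSE
  )
  planted_canon <- vapply(config$planted_events, function(ev)
    paste(ev$chrom, ev$canonical[1], ev$canonical[2]), character(1))

  with_seed(config$seed, {
    recs <- list()
    truth <- list()
    for (ev in config$planted_events) {
      cj <- junction_id(ev$chrom, ev$cryptic[1], ev$cryptic[2], ev$strand)
      for (g in config$genotypes) {
        p <- if (g %in% names(ev$psi)) unname(ev$psi[g]) else config$baseline_psi
        truth[[length(truth) + 1L]] <- data.frame(
          event_id = ev$event_id, junction = cj, genotype = g, true_psi = p,
          stringsAsFactors = FALSE)
      }
      for (i in seq_len(nrow(samples))) {
        g <- samples$genotype[i]
        p <- if (g %in% names(ev$psi)) unname(ev$psi[g]) else config$baseline_psi
        total <- stats::rpois(1, config$depth_per_anchor)
        cryptic_n <- rbetabinom(1, total, p, config$dispersion)
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = ev$chrom,
          intron_start = c(ev$canonical[1], ev$cryptic[1]),
          intron_end = c(ev$canonical[2], ev$cryptic[2]),
          strand = ev$strand,
          unique_count = c(total - cryptic_n, cryptic_n),
          sample_id = samples$sample_id[i],
          stringsAsFactors = FALSE)
      }
    }
    bg <- introns[!(ann_key %in% planted_canon), , drop = FALSE]
    if (nrow(bg)) {
      for (i in seq_len(nrow(samples))) {
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = bg$chrom,
          intron_start = bg$intron_start,
          intron_end = bg$intron_end,
          strand = bg$strand,
          unique_count = stats::rpois(nrow(bg), config$depth_per_anchor),
          sample_id = samples$sample_id[i],
          stringsAsFactors = FALSE)
      }
    }
    jx <- if (length(recs)) do.call(rbind, recs) else empty_junctions()
    rownames(jx) <- NULL
    structure(list(junctions = jx, sample_info = samples,
                   truth = if (length(truth)) do.call(rbind, truth) else NULL,
                   annotation = annotation, config = config),
              class = "splice_sim")
  })
}

#' Cohort-simulation configuration
#'
#' Defaults emulate the statistical structure of the pooled clinical
#' dataset: variant mixture proportional to the observed per-variant totals,
#' per-variant diagnosis distributions matching the published partitioning,
#' co-mutation probabilities matching the published frequencies (ASXL1
#' enriched and DNMT3A depleted with E592K, etc.), a ring-sideroblast model
#' in which exon 14-16 low-blast disease averages 37% RS while E592K cases
#' have almost none, and exponential survival with a markedly higher hazard
#' for E592K.
#'
#' @param n_cases number of patients
#' @param variant_probs named probability vector over SF3B1 variants
#' @param diagnosis_probs_by_variant named list: variant -> named probability
#'   vector over diagnoses (MDS-RS, MDS-SLD/MLD, MDS-EB, AML)
#' @param comutation_probs_by_variant named list: variant -> named vector of
#'   per-gene co-mutation probabilities
#' @param rs_percent_model named list: variant -> list(mean, sd,
#'   missing_rate) for ring-sideroblast percentage (truncated to [0, 100])
#' @param survival_hazards named list: variant -> c(os = rate, lfs = rate),
#'   per-year exponential event rates
#' @param censor_rate expected fraction of censored observations
#' @param seed integer seed
#' @return list of class `cohort_sim_config`
#' @export
cohort_sim_config <- function(
    n_cases = 2000L,
    variant_probs = NULL,
    diagnosis_probs_by_variant = NULL,
    comutation_probs_by_variant = NULL,
    rs_percent_model = NULL,
    survival_hazards = NULL,
    censor_rate = 0.3,
    seed = 1L) {
  if (is.null(variant_probs)) {
    tot <- c(K700E = 1820, K666N = 198, E622D = 102, K666R = 85, E592K = 29)
    variant_probs <- tot / sum(tot)
  }
  if (is.null(diagnosis_probs_by_variant)) {
    dx <- function(p) stats::setNames(p / sum(p),
                                      c("MDS-RS", "MDS-SLD/MLD", "MDS-EB", "AML"))
    diagnosis_probs_by_variant <- list(
      # per-variant distributions from the published counts
      K666N = dx(c(28, 21, 46, 103)),
      E592K = dx(c(1, 9, 9, 10)),
      E622D = dx(c(92, 7, 1, 2)),
      K666R = dx(c(72, 3, 3, 7)),
      K700E = dx(c(0.70, 0.15, 0.08, 0.07))
    )
  }
  if (is.null(comutation_probs_by_variant)) {
    e14_16 <- c(ASXL1 = 0.09, DNMT3A = 0.21, RUNX1 = 0.11, STAG2 = 0.03,
                TET2 = 0.25, SRSF2 = 0.05, EZH2 = 0.05, JAK2 = 0.05)
    comutation_probs_by_variant <- list(
      E592K = c(ASXL1 = 0.83, DNMT3A = 0.029, RUNX1 = 0.51, STAG2 = 0.29,
                TET2 = 0.25, SRSF2 = 0.05, EZH2 = 0.05, JAK2 = 0.05),
      K700E = e14_16, K666N = e14_16, K666R = e14_16, E622D = e14_16
    )
  }
  if (is.null(rs_percent_model)) {
    rs_e14_16 <- list(mean = 37, sd = 15, missing_rate = 0.2)
    rs_percent_model <- list(
      E592K = list(mean = 0.5, sd = 2, missing_rate = 0.2),
      K700E = rs_e14_16, K666N = rs_e14_16, K666R = rs_e14_16,
      E622D = rs_e14_16
    )
  }
  if (is.null(survival_hazards)) {
    # medians ~1.5y OS / ~0.9y LFS for E592K vs ~5y / ~4y otherwise
    hi <- c(os = log(2) / 1.5, lfs = log(2) / 0.9)
    lo <- c(os = log(2) / 5, lfs = log(2) / 4)
    survival_hazards <- list(E592K = hi, K700E = lo, K666N = lo,
                             K666R = lo, E622D = lo)
  }
  if (abs(sum(variant_probs) - 1) > 1e-9)
    stop("variant_probs must sum to 1")
  if (any(variant_probs < 0 | variant_probs > 1))
    stop("probabilities must lie in [0,1]")
  for (v in names(diagnosis_probs_by_variant)) {
    p <- diagnosis_probs_by_variant[[v]]
    if (abs(sum(p) - 1) > 1e-9) stop("diagnosis probs for ", v, " must sum to 1")
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  }
  for (v in names(comutation_probs_by_variant)) {
    p <- comutation_probs_by_variant[[v]]
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  }
  for (v in names(survival_hazards))
    if (any(survival_hazards[[v]] <= 0)) stop("hazards must be positive")
  stopifnot(censor_rate >= 0, censor_rate < 1, n_cases >= 0)
  structure(list(n_cases = as.integer(n_cases),
                 variant_probs = variant_probs,
                 diagnosis_probs_by_variant = diagnosis_probs_by_variant,
                 comutation_probs_by_variant = comutation_probs_by_variant,
                 rs_percent_model = rs_percent_model,
                 survival_hazards = survival_hazards,
                 censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

sf3b1_exon_of <- function(variant) {
  map <- c(E592K = 13L, E622D = 14L, R625H = 14L, K666N = 14L, K666R = 14L,
           K700E = 15L, K741N = 16L)
  out <- unname(map[variant])
  out[is.na(out)] <- NA_integer_
  out
}

#' The 35-gene myeloid panel used for co-mutation inclusion
#'
#' Cases are included in a gene's co-mutation denominators only when their
#' sequencing panel covered that gene; the default full panel has 35 genes.
#'
#' @return character vector of 35 gene symbols
#' @export
myeloid_panel_genes <- function() {
  c("ASXL1", "BCOR", "BCORL1", "CALR", "CBL", "CEBPA", "CSF3R", "DNMT3A",
    "ETV6", "EZH2", "FLT3", "GATA2", "IDH1", "IDH2", "JAK2", "KIT", "KRAS",
    "MPL", "NF1", "NPM1", "NRAS", "PHF6", "PPM1D", "PTPN11", "RAD21",
    "RUNX1", "SETBP1", "SF3B1", "SRSF2", "STAG2", "TET2", "TP53", "U2AF1",
    "WT1", "ZRSR2")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Simulate a clinical cohort
#'
#' Each case independently draws an SF3B1 variant, a diagnosis given the
#' variant, co-mutations with per-gene variant-dependent probabilities (each
#' with a VAF), ring-sideroblast and blast percentages, CBC values, an
#' IPSS-R score, a sequencing panel, and exponential overall/leukemia-free
#' survival times with independent exponential censoring calibrated to the
#' configured censoring fraction.
#'
#' @param config a [cohort_sim_config()]
#' @return data.frame of case records (one row per patient); `comutations`
#'   and `panel_genes` are list-columns
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_cases
  if (n == 0) return(empty_cohort())
  with_seed(config$seed, {
    variant <- sample(names(config$variant_probs), n, replace = TRUE,
                      prob = config$variant_probs)
    diagnosis <- vapply(variant, function(v) {
      p <- config$diagnosis_probs_by_variant[[v]]
      sample(names(p), 1, prob = p)
    }, character(1))
    genes <- unique(unlist(lapply(config$comutation_probs_by_variant, names)))
    full_panel <- union(myeloid_panel_genes(), genes)
    small_panel <- setdiff(genes, c("STAG2", "EZH2"))
    comut <- vector("list", n)
    panel <- vector("list", n)
    for (i in seq_len(n)) {
      pr <- config$comutation_probs_by_variant[[variant[i]]]
      hit <- names(pr)[stats::runif(length(pr)) < pr]
      comut[[i]] <- if (length(hit))
        data.frame(gene = hit,
                   vaf = round(stats::runif(length(hit), 0.05, 0.50), 3),
                   stringsAsFactors = FALSE)
      else data.frame(gene = character(), vaf = numeric())
      panel[[i]] <- if (stats::runif(1) < 0.8) full_panel else small_panel
    }
    rs <- numeric(n); rs_known <- logical(n)
    for (i in seq_len(n)) {
      m <- config$rs_percent_model[[variant[i]]]
      rs_known[i] <- stats::runif(1) >= m$missing_rate
      rs[i] <- if (rs_known[i]) rnorm_trunc(1, m$mean, m$sd, 0, 100) else NA_real_
    }
    blast <- ifelse(diagnosis == "AML", stats::runif(n, 20, 60),
                    ifelse(diagnosis == "MDS-EB", stats::runif(n, 5, 19),
                           stats::runif(n, 0, 4.9)))
    is_e592k <- variant == "E592K"
    platelets <- ifelse(is_e592k, rnorm_trunc(n, 100, 50, 5, 1000),
                        rnorm_trunc(n, 180, 80, 5, 1000))
    hemoglobin <- rnorm_trunc(n, 9.5, 1.5, 4, 16)
    anc <- round(exp(stats::rnorm(n, log(1.8), 0.5)), 2)
    ipss_r <- ifelse(is_e592k, rnorm_trunc(n, 4.5, 1.2, 0, 10),
                     rnorm_trunc(n, 3.0, 1.2, 0, 10))
    surv_draw <- function(kind) {
      rate <- vapply(variant, function(v) config$survival_hazards[[v]][kind],
                     numeric(1))
      t_event <- stats::rexp(n, rate)
      c_rate <- rate * config$censor_rate / (1 - config$censor_rate)
      t_cens <- if (config$censor_rate > 0) stats::rexp(n, c_rate) else rep(Inf, n)
      list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
    }
    os <- surv_draw("os")
    lfs <- surv_draw("lfs")
    out <- data.frame(
      case_id = sprintf("case_%04d", seq_len(n)),
      diagnosis = diagnosis,
      sf3b1_variant = variant,
      sf3b1_exon = sf3b1_exon_of(variant),
      rs_percent = rs,
      blast_percent = round(blast, 1),
      platelets = round(platelets),
      hemoglobin = round(hemoglobin, 1),
      anc = anc,
      ipss_r = round(ipss_r, 2),
      os_time = round(os$time, 4), os_event = os$event,
      lfs_time = round(lfs$time, 4), lfs_event = lfs$event,
      stringsAsFactors = FALSE
    )
    out$comutations <- comut
    out$panel_genes <- panel
    rownames(out) <- NULL
    out
  })
}

empty_cohort <- function() {
  out <- data.frame(case_id = character(), diagnosis = character(),
                    sf3b1_variant = character(), sf3b1_exon = integer(),
                    rs_percent = numeric(), blast_percent = numeric(),
                    platelets = numeric(), hemoglobin = numeric(),
                    anc = numeric(), ipss_r = numeric(),
                    os_time = numeric(), os_event = logical(),
                    lfs_time = numeric(), lfs_event = logical(),
                    stringsAsFactors = FALSE)
  out$comutations <- list()
  out$panel_genes <- list()
  out
}

#' Write simulation fixtures to disk
#'
#' Emits a GTF annotation, one STAR-dialect `SJ.out.tab` junction table per
#' sample, a sample-info TSV, a planted-truth TSV, and a cohort TSV. Every
#' writer stamps the generating seed into a header comment. The files
#' round-trip losslessly through [read_gtf()], [read_junction_table()] and
#' [read_cohort_table()].
#'
#' @param annotation a [toy_annotation()] (or NULL to skip)
#' @param sim a `splice_sim` from [simulate_junction_counts()] (or NULL)
#' @param cases a cohort data.frame from [simulate_cohort()] (or NULL)
#' @param out_dir output directory (created if needed)
#' @param seed seed stamped into headers
#' @return named character vector of the paths written
#' @export
write_fixtures <- function(annotation = NULL, sim = NULL, cases = NULL,
                           out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character()
  hdr <- sprintf("#cryptsplice fixture seed=%s", seed)
  if (!is.null(annotation)) {
    p <- file.path(out_dir, "annotation.gtf")
    write_gtf(annotation, p, seed = if (is.na(seed)) NULL else seed)
    paths["gtf"] <- p
  }
  if (!is.null(sim)) {
    for (s in sim$sample_info$sample_id) {
      jx <- sim$junctions[sim$junctions$sample_id == s, , drop = FALSE]
      p <- file.path(out_dir, paste0(s, ".SJ.out.tab"))
      strand_code <- c("*" = 0L, "+" = 1L, "-" = 2L)[jx$strand]
      lines <- sprintf("%s\t%d\t%d\t%d\t0\t1\t%d\t0\t50",
                       jx$chrom, jx$intron_start, jx$intron_end,
                       strand_code, jx$unique_count)
      writeLines(c(hdr, lines), p)
      paths[paste0("sj_", s)] <- p
    }
    p <- file.path(out_dir, "samples.tsv")
    write_tsv_commented(sim$sample_info, p, hdr)
    paths["samples"] <- p
    if (!is.null(sim$truth)) {
      p <- file.path(out_dir, "truth.tsv")
      write_tsv_commented(sim$truth, p, hdr)
      paths["truth"] <- p
    }
  }
  if (!is.null(cases)) {
    p <- file.path(out_dir, "cohort.tsv")
    write_cohort_table(cases, p, header_comment = hdr)
    paths["cohort"] <- p
  }
  paths
}

write_tsv_commented <- function(df, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Plant one hotspot-specific cryptic event per annotated intron
#'
#' Distributes alternative 3' acceptor events over the annotation's introns,
#' cycling through the non-reference genotypes so each event is elevated in
#' exactly one hotspot and stays at the wild-type baseline in the others.
#'
#' @param annotation a [toy_annotation()]
#' @param genotypes non-reference genotypes to cycle through
#' @param n_per_genotype events planted per genotype
#' @param psi_mut cryptic PSI in the event's own genotype
#' @param shift acceptor displacement into the intron (nt)
#' @param baseline_psi cryptic PSI everywhere else
#' @return list of planted events for [splice_sim_config()]
#' @export
plant_hotspot_events <- function(annotation, genotypes = c("K700E", "E592K"),
                                 n_per_genotype = 10L, psi_mut = 0.5,
                                 shift = 20L, baseline_psi = 0.02) {
  introns <- annotated_introns(annotation)
  need <- n_per_genotype * length(genotypes)
  if (nrow(introns) < need)
    stop("annotation has ", nrow(introns), " introns; need ", need)
  events <- vector("list", need)
  for (k in seq_len(need)) {
    g <- genotypes[((k - 1L) %% length(genotypes)) + 1L]
    it <- introns[k, ]
    psi <- stats::setNames(rep(baseline_psi, length(genotypes) + 1L),
                           c("WT", genotypes))
    psi[g] <- psi_mut
    events[[k]] <- plant_alt_acceptor(
      annotation, it$transcript_id, it$intron_index, shift, psi,
      event_id = sprintf("%s.i%d.%s", it$transcript_id, it$intron_index, g))
  }
  events
}
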