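# Orchestrates simulate -> psi -> diff -> classify -> cohort -> report with
# file-persisted stage boundaries, a validated configuration, and a run
# manifest sufficient to reproduce every output.

pipeline_schema <- function() {
  list(
    out_dir = "character", seed = "numeric", log_level = "character",
    simulate = list(
      genotypes = "character", n_samples_per_genotype = "numeric",
      depth_per_anchor = "numeric", dispersion = "numeric",
      n_events_per_genotype = "numeric", psi_mut = "numeric",
      shift = "numeric", baseline_psi = "numeric",
      n_genes = "numeric", n_cases = "numeric", censor_rate = "numeric"
    ),
    quant = list(min_coverage = "numeric", min_samples_per_group = "numeric"),
    diff = list(reference_genotype = "character", top_k = "numeric"),
    classify = list(t_present = "numeric", t_absent = "numeric",
                    nmd_rule_nt = "numeric")
  )
}

validate_config <- function(config, schema = pipeline_schema(), path = "") {
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("unknown config key(s): ",
         paste(paste0(path, bad), collapse = ", "))
  for (k in names(config)) {
    if (is.list(schema[[k]])) {
      if (!is.list(config[[k]]))
        stop("config key ", path, k, " must be a mapping")
      validate_config(config[[k]], schema[[k]], paste0(path, k, "."))
    } else {
      ok <- switch(schema[[k]],
                   numeric = is.numeric(config[[k]]),
                   character = is.character(config[[k]]),
                   FALSE)
      if (!ok) stop("config key ", path, k, " must be ", schema[[k]])
    }
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' @param out_dir output directory for all stage artifacts
#' @param seed master seed for every randomized stage
#' @return nested configuration list accepted by [run_pipeline()]
#' @export
default_run_config <- function(out_dir = tempfile("cryptsplice_run_"),
                               seed = 1L) {
  list(
    out_dir = out_dir, seed = as.numeric(seed), log_level = "info",
    simulate = list(
      genotypes = c("WT", "K700E", "E592K"),
      n_samples_per_genotype = 4, depth_per_anchor = 200, dispersion = 0.01,
      n_events_per_genotype = 10, psi_mut = 0.5, shift = 20,
      baseline_psi = 0.02, n_genes = 20, n_cases = 400, censor_rate = 0.3
    ),
    quant = list(min_coverage = 15, min_samples_per_group = 2),
    diff = list(reference_genotype = "WT", top_k = 50),
    classify = list(t_present = 0.10, t_absent = 0.05, nmd_rule_nt = 50)
  )
}

pipe_log <- function(level, cfg, ...) {
  lv <- cfg$log_level %||% "info"
  if (lv == "quiet") return(invisible())
  message(sprintf("[cryptsplice %s] %s", level, paste0(...)))
}

need_file <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing upstream artifact: ", path)
  path
}

read_psi_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$junction
  m
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, persisting every stage
#' boundary as a file under `config$out_dir`:
#' \describe{
#'   \item{simulate}{toy annotation (GTF), per-sample junction tables,
#'     sample table, planted truth, simulated cohort}
#'   \item{psi}{PSI matrix with the coverage filter applied}
#'   \item{diff}{differential PSI table versus the reference genotype}
#'   \item{classify}{ranked events with class/frame/PTC/NMD annotation,
#'     specificity labels, Jaccard overlap summary, BED of cryptic junctions}
#'   \item{cohort}{variant-by-diagnosis partitioning and exact tests,
#'     co-mutation landscape (E592K vs exon 14-16), clinical comparisons, RS
#'     summaries, KM curves, log-rank tests, oncoprint matrix}
#'   \item{report}{machine-readable run manifest (config, seeds, versions,
#'     md5 of every artifact)}
#' }
#' Rerunning with an identical configuration reproduces identical artifacts.
#'
#' @param config configuration list (see [default_run_config()]) or path to
#'   a YAML file with the same structure; unknown keys are rejected
#' @param stages which stages to run, in any order (dependency order is
#'   enforced internally)
#' @return named list of artifact paths, invisibly
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "psi", "diff", "classify",
                                    "cohort", "report")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  validate_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  stages <- match.arg(stages, several.ok = TRUE)
  order_all <- c("simulate", "psi", "diff", "classify", "cohort", "report")
  stages <- order_all[order_all %in% stages]
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- character()
  p <- function(f) file.path(out, f)

  if ("simulate" %in% stages) {
    pipe_log("info", cfg, "simulate: annotation, junction tables, cohort")
    ann <- tiled_annotation(cfg$simulate$n_genes)
    events <- plant_hotspot_events(
      ann, genotypes = setdiff(cfg$simulate$genotypes, "WT"),
      n_per_genotype = cfg$simulate$n_events_per_genotype,
      psi_mut = cfg$simulate$psi_mut, shift = cfg$simulate$shift,
      baseline_psi = cfg$simulate$baseline_psi)
    scfg <- splice_sim_config(
      genotypes = cfg$simulate$genotypes,
      n_samples_per_genotype = cfg$simulate$n_samples_per_genotype,
      depth_per_anchor = cfg$simulate$depth_per_anchor,
      dispersion = cfg$simulate$dispersion,
      planted_events = events, baseline_psi = cfg$simulate$baseline_psi,
      seed = cfg$seed)
    sim <- simulate_junction_counts(ann, scfg)
    cases <- simulate_cohort(cohort_sim_config(
      n_cases = cfg$simulate$n_cases, censor_rate = cfg$simulate$censor_rate,
      seed = cfg$seed))
    paths <- c(paths, write_fixtures(ann, sim, cases, out, seed = cfg$seed))
  }

  if ("psi" %in% stages) {
    pipe_log("info", cfg, "psi: anchor groups and PSI matrix")
    ann <- read_gtf(need_file(p("annotation.gtf"), "psi"))
    sj <- list.files(out, pattern = "\\.SJ\\.out\\.tab$", full.names = TRUE)
    if (!length(sj)) stop("stage 'psi' needs junction tables (*.SJ.out.tab) in ", out)
    jx <- do.call(rbind, lapply(sj, function(f)
      read_junction_table(f, sample_id = sub("\\.SJ\\.out\\.tab$", "", basename(f)))))
    groups <- build_anchor_groups(jx, ann)
    psi <- compute_psi(groups, jx, quant_config(cfg$quant$min_coverage,
                                                cfg$quant$min_samples_per_group))
    paths["psi"] <- write_psi_matrix(psi, p("psi_matrix.tsv"))
  }

  if ("diff" %in% stages) {
    pipe_log("info", cfg, "diff: delta PSI vs ", cfg$diff$reference_genotype)
    m <- read_psi_table(need_file(p("psi_matrix.tsv"), "diff"))
    si <- utils::read.delim(need_file(p("samples.tsv"), "diff"),
                            comment.char = "#")
    gmap <- stats::setNames(si$genotype, si$sample_id)
    res <- delta_psi(structure(list(psi = m), class = "psi_matrix"),
                     gmap, cfg$diff$reference_genotype,
                     quant_config(cfg$quant$min_coverage,
                                  cfg$quant$min_samples_per_group))
    utils::write.table(res, p("differential.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths["diff"] <- p("differential.tsv")
  }

  if ("classify" %in% stages) {
    pipe_log("info", cfg, "classify: ranking, event classes, specificity")
    res <- utils::read.delim(need_file(p("differential.tsv"), "classify"),
                             na.strings = "NA")
    ann <- read_gtf(need_file(p("annotation.gtf"), "classify"))
    ranked <- rank_events(res, top_k = cfg$diff$top_k)
    ranked <- annotate_events(ranked, ann,
                              nmd_rule_nt = cfg$classify$nmd_rule_nt)
    spec <- call_specificity(res, t_present = cfg$classify$t_present,
                             t_absent = cfg$classify$t_absent,
                             min_informative = cfg$quant$min_samples_per_group)
    ranked <- merge(ranked, spec$calls, by = "junction", sort = FALSE)
    ranked <- ranked[order(-ranked$score, ranked$junction), , drop = FALSE]
    utils::write.table(ranked, p("events.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(spec$jaccard, p("overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    write_events_bed(ranked, p("events.bed"))
    paths <- c(paths, events = p("events.tsv"), overlap = p("overlap.tsv"),
               bed = p("events.bed"))
  }

  if ("cohort" %in% stages) {
    pipe_log("info", cfg, "cohort: partitioning, co-mutation, survival")
    cases <- read_cohort_table(need_file(p("cohort.tsv"), "cohort"))
    part <- partition_distribution(cases)
    utils::write.table(part$table, p("partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    if (!is.null(part$tests))
      utils::write.table(part$tests, p("partition_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
    is_e592k <- function(case) case$sf3b1_variant == "E592K"
    is_e14_16 <- function(case) !is.na(case$sf3b1_exon) &&
      case$sf3b1_exon >= 14 && case$sf3b1_exon <= 16
    genes <- sort(unique(unlist(lapply(cases$comutations, function(x) x$gene))))
    if (length(genes) && any(vapply(seq_len(nrow(cases)), function(i)
      isTRUE(is_e592k(cases[i, ])), logical(1)))) {
      cm <- comutation_landscape(cases, is_e592k, is_e14_16, genes = genes,
                                 cohort_names = c("e592k", "e14_16"))
      utils::write.table(cm, p("comutation.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      paths["comutation"] <- p("comutation.tsv")
    }
    clin <- lapply(c("ipss_r", "platelets", "hemoglobin"), function(f) {
      r <- compare_clinical(cases, is_e592k, is_e14_16, f)
      data.frame(field = f, p_value = r$p_value, median_e592k = r$median_a,
                 median_e14_16 = r$median_b, n_e592k = r$n_a,
                 n_e14_16 = r$n_b)
    })
    utils::write.table(do.call(rbind, clin), p("clinical_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    rs <- summarize_rs(cases, function(case)
      is_e14_16(case) && !is.na(case$blast_percent) && case$blast_percent < 5)
    writeLines(sprintf("mean_rs_exon14_16_low_blast\t%s\tn\t%d",
                       format(rs$mean_rs), rs$n), p("rs_summary.tsv"))
    surv_rows <- list()
    for (endpoint in c("os", "lfs")) {
      t_col <- paste0(endpoint, "_time"); e_col <- paste0(endpoint, "_event")
      sel <- cases$sf3b1_variant == "E592K"
      lr <- logrank_test(cases[[t_col]][sel], cases[[e_col]][sel],
                         cases[[t_col]][!sel], cases[[e_col]][!sel])
      km_a <- km_estimate(cases[[t_col]][sel], cases[[e_col]][sel])
      km_b <- km_estimate(cases[[t_col]][!sel], cases[[e_col]][!sel])
      curve_df <- function(km, grp) data.frame(
        endpoint = endpoint, group = grp, time = km$time, surv = km$surv,
        n_risk = km$n_risk, n_event = km$n_event)
      surv_rows[[endpoint]] <- list(
        curves = rbind(curve_df(km_a, "E592K"), curve_df(km_b, "other")),
        test = data.frame(endpoint = endpoint, chisq = lr$chisq,
                          p_value = lr$p_value,
                          median_e592k = km_a$median, median_other = km_b$median))
    }
    utils::write.table(do.call(rbind, lapply(surv_rows, `[[`, "curves")),
                       p("survival_curves.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(do.call(rbind, lapply(surv_rows, `[[`, "test")),
                       p("logrank.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    om <- oncoprint_matrix(cases)
    utils::write.table(data.frame(gene = rownames(om), om, check.names = FALSE),
                       p("oncoprint.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, partition = p("partition.tsv"),
               clinical = p("clinical_tests.tsv"),
               survival = p("survival_curves.tsv"), logrank = p("logrank.tsv"),
               oncoprint = p("oncoprint.tsv"), rs = p("rs_summary.tsv"))
  }

  if ("report" %in% stages) {
    pipe_log("info", cfg, "report: manifest")
    arts <- setdiff(list.files(out, full.names = TRUE),
                    file.path(out, "manifest.json"))
    manifest <- list(
      package = "cryptsplice",
      version = as.character(utils::packageVersion("cryptsplice")),
      seed = cfg$seed,
      config = cfg,
      artifacts = lapply(stats::setNames(arts, basename(arts)),
                         function(f) list(md5 = unname(tools::md5sum(f))))
    )
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    paths["manifest"] <- p("manifest.json")
  }
  invisible(paths)
}
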