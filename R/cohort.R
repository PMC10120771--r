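# Hotspot-resolved clinical statistics: variant x diagnosis partitioning,
# WHO 2016 ring-sideroblast criteria, co-mutation landscape with exact tests
# and FDR, rank-based clinical comparisons, and KM/log-rank survival.

#' Write / read the cohort table
#'
#' Column dictionary (TSV, one row per patient): case_id; diagnosis (MDS-RS,
#' MDS-SLD/MLD, MDS-EB, AML, other); sf3b1_variant; sf3b1_exon; comutations
#' (semicolon-separated `GENE:VAF` pairs, empty if none); panel_genes
#' (comma-separated symbols sequenced for this case); rs_percent (0-100, NA
#' if unknown); blast_percent; platelets (10^9/L); hemoglobin (g/dL); anc
#' (10^9/L); ipss_r; os_time/lfs_time (years); os_event/lfs_event (TRUE =
#' event observed, FALSE = censored).
#'
#' @param cases cohort data.frame as from [simulate_cohort()]
#' @param path output file
#' @param header_comment optional `#`-prefixed first line
#' @return `path`, invisibly
#' @export
write_cohort_table <- function(cases, path, header_comment = NULL) {
  flat <- cases
  flat$comutations <- vapply(cases$comutations, function(cm) {
    if (is.null(cm) || !nrow(cm)) "" else
      paste(sprintf("%s:%s", cm$gene, format(cm$vaf, trim = TRUE)),
            collapse = ";")
  }, character(1))
  flat$panel_genes <- vapply(cases$panel_genes, paste, character(1),
                             collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(header_comment, con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  flat <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                            na.strings = "NA")
  flat$comutations <- lapply(flat$comutations, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(gene = character(), vaf = numeric()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(gene = vapply(parts, `[`, "", 1L),
               vaf = as.numeric(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  flat$panel_genes <- lapply(flat$panel_genes, function(s) {
    if (is.na(s) || !nzchar(s)) character() else
      strsplit(s, ",", fixed = TRUE)[[1]]
  })
  flat
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (within relative tolerance 1e-7). When any margin is zero
#' the test is degenerate: p = 1 by convention and the result is flagged.
#' The odds ratio is the sample ad/bc when all cells are positive; with a
#' zero cell the conditional-maximum-likelihood estimate and a
#' 0.5-continuity-corrected ratio are reported instead.
#'
#' @param tab 2x2 non-negative integer matrix
#' @return list: p_value, odds_ratio (sample or CMLE), odds_ratio_cc
#'   (0.5-corrected, only when a cell is 0), degenerate flag
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1.0, odds_ratio = NA_real_, odds_ratio_cc = NA_real_,
                degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  if (all(tab > 0)) {
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    or_cc <- NA_real_
  } else {
    or <- unname(ft$estimate)  # conditional MLE
    or_cc <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  }
  list(p_value = ft$p.value, odds_ratio = or, odds_ratio_cc = or_cc,
       degenerate = FALSE)
}

#' Variant-by-diagnosis partitioning with pairwise exact tests
#'
#' For each variant of interest, counts and percentages per diagnosis
#' (percentage = 100 x variant count / diagnosis total, printed half-up to
#' one decimal, two decimals below 0.1%), and for every pair of diagnoses a
#' two-sided Fisher exact test on the 2x2 of (variant vs all other variants)
#' x (diagnosis A vs diagnosis B).
#'
#' @param cases cohort data.frame (columns diagnosis, sf3b1_variant)
#' @param variants_of_interest variants to tabulate (default: all observed)
#' @param diagnoses diagnosis order (default: all observed)
#' @return list: `table` (variant, diagnosis, count, total, percent,
#'   percent_printed, undefined flag) and `tests` (variant, diagnosis_a,
#'   diagnosis_b, p_value, odds_ratio)
#' @export
partition_distribution <- function(cases, variants_of_interest = NULL,
                                   diagnoses = NULL) {
  stopifnot(all(c("diagnosis", "sf3b1_variant") %in% names(cases)))
  variants <- variants_of_interest %||% sort(unique(cases$sf3b1_variant))
  dxs <- diagnoses %||% sort(unique(cases$diagnosis))
  rows <- list(); tests <- list()
  for (v in variants) {
    for (d in dxs) {
      total <- sum(cases$diagnosis == d)
      count <- sum(cases$diagnosis == d & cases$sf3b1_variant == v)
      pct <- if (total > 0) 100 * count / total else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, diagnosis = d, count = count, total = total,
        percent = pct, percent_printed = format_percent(pct),
        undefined = total == 0, stringsAsFactors = FALSE)
    }
    if (length(dxs) > 1) {
      for (i in seq_len(length(dxs) - 1)) for (j in seq(i + 1, length(dxs))) {
        a <- dxs[i]; b <- dxs[j]
        tab <- matrix(c(
          sum(cases$diagnosis == a & cases$sf3b1_variant == v),
          sum(cases$diagnosis == a & cases$sf3b1_variant != v),
          sum(cases$diagnosis == b & cases$sf3b1_variant == v),
          sum(cases$diagnosis == b & cases$sf3b1_variant != v)), 2)
        ft <- fisher_exact_two_sided(tab)
        tests[[length(tests) + 1L]] <- data.frame(
          variant = v, diagnosis_a = a, diagnosis_b = b,
          p_value = ft$p_value, odds_ratio = ft$odds_ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, rows),
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

star_tier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Co-mutation landscape between two cohorts
#'
#' Per-gene mutation frequencies in the two cohorts defined by an SF3B1
#' variant predicate, with two-sided Fisher exact tests, raw-p star tiers
#' and Benjamini-Hochberg q-values. A case enters a gene's denominators only
#' if its sequencing panel covered that gene; cases whose panel lacks the
#' gene are excluded from that gene only.
#'
#' @param cases cohort data.frame with list-columns `comutations` and
#'   `panel_genes`
#' @param predicate_a,predicate_b functions CaseRecord-row -> logical
#'   defining the two cohorts (e.g. E592K vs exon 14-16)
#' @param genes genes to test (default: the 35-gene panel minus SF3B1)
#' @param cohort_names labels for the two cohorts
#' @return data.frame: gene, n_a, mut_a, freq_a, n_b, mut_b, freq_b,
#'   p_value, odds_ratio, stars, q_value
#' @export
comutation_landscape <- function(cases, predicate_a, predicate_b,
                                 genes = setdiff(myeloid_panel_genes(), "SF3B1"),
                                 cohort_names = c("a", "b")) {
  in_a <- vapply(seq_len(nrow(cases)), function(i) isTRUE(predicate_a(cases[i, ])),
                 logical(1))
  in_b <- vapply(seq_len(nrow(cases)), function(i) isTRUE(predicate_b(cases[i, ])),
                 logical(1))
  if (!any(in_a) || !any(in_b))
    stop("empty cohort after applying the variant predicate")
  has_gene_panel <- function(i, g) g %in% cases$panel_genes[[i]]
  mutated <- function(i, g) g %in% cases$comutations[[i]]$gene
  rows <- list()
  for (g in genes) {
    covered <- vapply(seq_len(nrow(cases)), has_gene_panel, logical(1), g = g)
    ia <- which(in_a & covered); ib <- which(in_b & covered)
    if (!length(ia) || !length(ib))
      stop("no panel-covered cases for gene ", g, " in one cohort")
    ma <- sum(vapply(ia, mutated, logical(1), g = g))
    mb <- sum(vapply(ib, mutated, logical(1), g = g))
    ft <- fisher_exact_two_sided(matrix(c(ma, length(ia) - ma,
                                          mb, length(ib) - mb), 2))
    rows[[g]] <- data.frame(
      gene = g, n_a = length(ia), mut_a = ma, freq_a = 100 * ma / length(ia),
      n_b = length(ib), mut_b = mb, freq_b = 100 * mb / length(ib),
      p_value = ft$p_value, odds_ratio = ft$odds_ratio,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$stars <- star_tier(out$p_value)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  names(out)[names(out) == "n_a"] <- paste0("n_", cohort_names[1])
  names(out)[names(out) == "mut_a"] <- paste0("mut_", cohort_names[1])
  names(out)[names(out) == "freq_a"] <- paste0("freq_", cohort_names[1])
  names(out)[names(out) == "n_b"] <- paste0("n_", cohort_names[2])
  names(out)[names(out) == "mut_b"] <- paste0("mut_", cohort_names[2])
  names(out)[names(out) == "freq_b"] <- paste0("freq_", cohort_names[2])
  rownames(out) <- NULL
  out
}

#' Oncoprint matrix (genes x cases, 0/1 mutation presence)
#'
#' @param cases cohort data.frame with list-column `comutations`
#' @param genes genes to include (default: all mutated genes observed)
#' @return integer matrix, genes in rows, case_ids in columns
#' @export
oncoprint_matrix <- function(cases, genes = NULL) {
  all_genes <- genes %||%
    sort(unique(unlist(lapply(cases$comutations, function(cm) cm$gene))))
  m <- matrix(0L, nrow = length(all_genes), ncol = nrow(cases),
              dimnames = list(all_genes, cases$case_id))
  for (i in seq_len(nrow(cases))) {
    g <- intersect(cases$comutations[[i]]$gene, all_genes)
    m[g, i] <- 1L
  }
  m
}

#' WHO 2016 ring-sideroblast diagnosis-eligibility flags
#'
#' MDS-RS eligibility through the mutated pathway requires an SF3B1 mutation
#' and strictly more than 5% ring sideroblasts; the unmutated pathway
#' requires strictly more than 15% RS. Unknown RS leaves both flags NA.
#'
#' @param rs_percent ring-sideroblast percentage (0-100) or NA
#' @param sf3b1_mutated logical
#' @return list: eligible_mutated_pathway, eligible_unmutated_pathway
#'   (logicals, NA when RS unknown)
#' @export
apply_rs_criterion <- function(rs_percent, sf3b1_mutated) {
  if (is.na(rs_percent))
    return(list(eligible_mutated_pathway = NA,
                eligible_unmutated_pathway = NA))
  list(eligible_mutated_pathway = isTRUE(sf3b1_mutated) && rs_percent > 5,
       eligible_unmutated_pathway = rs_percent > 15)
}

#' Mean ring-sideroblast percentage over a case subset
#'
#' @param cases cohort data.frame
#' @param predicate function row -> logical selecting cases
#' @return list: mean_rs, n (cases with known RS among selected), defined
#' @export
summarize_rs <- function(cases, predicate) {
  sel <- vapply(seq_len(nrow(cases)), function(i) isTRUE(predicate(cases[i, ])),
                logical(1))
  rs <- cases$rs_percent[sel]
  rs <- rs[!is.na(rs)]
  if (!length(rs))
    return(list(mean_rs = NA_real_, n = 0L, defined = FALSE))
  list(mean_rs = mean(rs), n = length(rs), defined = TRUE)
}

#' Rank-based comparison of a clinical parameter between two groups
#'
#' Two-sided Mann-Whitney test (exact for small untied samples, otherwise
#' the tie-corrected normal approximation), with medians and IQRs. If every
#' value is tied across both groups the comparison is degenerate and p = 1.
#'
#' @param cases cohort data.frame
#' @param predicate_a,predicate_b row predicates defining the groups
#' @param field column name of the parameter to compare
#' @return list: p_value, median_a, iqr_a, n_a, median_b, iqr_b, n_b,
#'   degenerate
#' @export
compare_clinical <- function(cases, predicate_a, predicate_b, field) {
  stopifnot(field %in% names(cases))
  sel <- function(pred) {
    idx <- vapply(seq_len(nrow(cases)), function(i) isTRUE(pred(cases[i, ])),
                  logical(1))
    x <- cases[[field]][idx]
    x[!is.na(x)]
  }
  a <- sel(predicate_a); b <- sel(predicate_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two known values per group for field ", field)
  summ <- function(x) list(median = stats::median(x),
                           iqr = unname(stats::quantile(x, c(0.25, 0.75))))
  if (length(unique(c(a, b))) == 1) {
    p <- 1.0; degenerate <- TRUE
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                             correct = FALSE)$p.value)
    degenerate <- FALSE
  }
  sa <- summ(a); sb <- summ(b)
  list(p_value = p, median_a = sa$median, iqr_a = sa$iqr, n_a = length(a),
       median_b = sb$median, iqr_b = sb$iqr, n_b = length(b),
       degenerate = degenerate)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (>= 0)
#' @param events TRUE = event observed, FALSE = censored
#' @return list of class `survival_curve`: time (ordered distinct event
#'   times), surv (step values), n_risk, n_event, median (smallest observed
#'   time with survival <= 0.5, NA if the curve never reaches 0.5)
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  keep <- fit$n.event > 0
  time <- fit$time[keep]; surv <- fit$surv[keep]
  med <- if (any(surv <= 0.5)) min(time[surv <= 0.5]) else NA_real_
  structure(list(time = time, surv = surv,
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median = med, n = length(times)),
            class = "survival_curve")
}

#' Log-rank (Mantel-Cox) test between two survival groups
#'
#' @param time_a,event_a times and event indicators of group A
#' @param time_b,event_b times and event indicators of group B
#' @return list: chisq (1 df), p_value, n_a, n_b, defined (FALSE when no
#'   event occurs in either group)
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0)
    return(list(chisq = NA_real_, p_value = NA_real_,
                n_a = length(time_a), n_b = length(time_b), defined = FALSE))
  grp <- c(rep("a", length(time_a)), rep("b", length(time_b)))
  sd <- survival::survdiff(
    survival::Surv(c(time_a, time_b), as.logical(c(event_a, event_b))) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_a = length(time_a), n_b = length(time_b), defined = TRUE)
}
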