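# Differential splicing between genotype groups, event ranking, cryptic
# splice-site classification, reading-frame/PTC/NMD prediction, and
# hotspot-specificity calls.

#' Differential PSI between genotype groups
#'
#' Per junction: mean PSI over non-missing samples in each genotype, the
#' count of informative samples, and the signed difference of means versus
#' the reference genotype. A junction enters the comparison only when the
#' reference and at least one other genotype reach
#' `config$min_samples_per_group` informative samples; genotypes below that
#' bar get an NA delta (indeterminate, not zero). The ranking score is the
#' largest absolute delta across non-reference genotypes. An optional
#' two-sided rank-sum p-value per genotype is reported for reference but not
#' used for ranking (group sizes of ~4 clones make test statistics
#' unstable).
#'
#' @param psi a `psi_matrix` from [compute_psi()]
#' @param genotype_map named character vector sample_id -> genotype
#' @param reference_genotype reference label (usually "WT")
#' @param config a [quant_config()]
#' @param rank_sum_p also compute per-genotype Wilcoxon p-values
#' @return data.frame with one row per junction: junction, mean_/n_ per
#'   genotype, delta_/p_ per non-reference genotype, score, indeterminate
#' @export
delta_psi <- function(psi, genotype_map, reference_genotype,
                      config = quant_config(), rank_sum_p = FALSE) {
  m <- psi$psi
  samples <- colnames(m)
  if (!all(samples %in% names(genotype_map)))
    stop("genotype missing for sample(s): ",
         paste(setdiff(samples, names(genotype_map)), collapse = ", "))
  geno <- genotype_map[samples]
  gts <- unique(geno)
  if (!reference_genotype %in% gts)
    stop("reference genotype ", reference_genotype, " has no samples")
  others <- setdiff(gts, reference_genotype)
  out <- data.frame(junction = rownames(m), stringsAsFactors = FALSE)
  means <- list(); ns <- list()
  for (g in gts) {
    sub <- m[, geno == g, drop = FALSE]
    means[[g]] <- rowMeans(sub, na.rm = TRUE)
    means[[g]][!is.finite(means[[g]])] <- NA_real_
    ns[[g]] <- rowSums(!is.na(sub))
    out[[paste0("mean_", g)]] <- means[[g]]
    out[[paste0("n_", g)]] <- ns[[g]]
  }
  ref_ok <- ns[[reference_genotype]] >= config$min_samples_per_group
  any_other_ok <- rep(FALSE, nrow(m))
  for (g in others) {
    ok <- ref_ok & ns[[g]] >= config$min_samples_per_group
    any_other_ok <- any_other_ok | ok
    d <- means[[g]] - means[[reference_genotype]]
    d[!ok] <- NA_real_
    out[[paste0("delta_", g)]] <- d
    if (rank_sum_p) {
      pv <- rep(NA_real_, nrow(m))
      ref_cols <- which(geno == reference_genotype)
      g_cols <- which(geno == g)
      for (i in which(ok)) {
        a <- m[i, g_cols]; b <- m[i, ref_cols]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(unique(c(a, b))) > 1)
          pv[i] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
        else pv[i] <- 1.0
      }
      out[[paste0("p_", g)]] <- pv
    }
  }
  deltas <- as.matrix(out[, paste0("delta_", others), drop = FALSE])
  score <- apply(abs(deltas), 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out$score <- score
  out$indeterminate <- !any_other_ok
  rownames(out) <- NULL
  out
}

#' Rank differential-splicing results
#'
#' Descending by score; ties broken by (chrom, intron_start, intron_end) so
#' the order is stable across runs. Indeterminate junctions (NA score) are
#' dropped.
#'
#' @param results data.frame from [delta_psi()]
#' @param top_k number of events to keep (default: all)
#' @return the top_k rows in rank order
#' @export
rank_events <- function(results, top_k = nrow(results)) {
  if (!nrow(results)) stop("no results to rank")
  if (top_k <= 0) stop("top_k must be positive")
  res <- results[!is.na(results$score), , drop = FALSE]
  coords <- parse_junction_id(res$junction)
  ord <- order(-res$score, coords$chrom, coords$intron_start, coords$intron_end)
  res <- res[ord, , drop = FALSE]
  utils::head(res, top_k)
}

#' Classify a cryptic junction against the annotation
#'
#' Shares a donor with an annotated intron while the acceptor differs:
#' alternative 3' acceptor. Shares the acceptor while the donor differs:
#' alternative 5' donor. Donor and acceptor match two different introns of
#' the same transcript: exon skip. Strictly inside an annotated intron,
#' touching neither end: intron retention proxy (junction evidence cannot
#' see retention directly). Identical to an annotated intron: degenerate
#' (not an event). Anything else: other.
#'
#' `inserted_or_deleted_nt` is the signed change in mature-transcript length
#' relative to canonical splicing (an acceptor shifted into the intron is a
#' positive insertion); `frame_shift` is TRUE iff that change is not a
#' multiple of 3.
#'
#' @param chrom,intron_start,intron_end,strand the cryptic junction
#' @param annotation a [toy_annotation()]
#' @return list: event_class, canonical_partner (junction id or NA),
#'   inserted_or_deleted_nt, frame_shift, gene_id, transcript_id
#' @export
classify_event <- function(chrom, intron_start, intron_end, strand, annotation) {
  introns <- annotated_introns(annotation)
  introns <- introns[introns$chrom == chrom & introns$strand == strand, ,
                     drop = FALSE]
  d <- anchor_pos(intron_start, intron_end, strand, "donor")
  a <- anchor_pos(intron_start, intron_end, strand, "acceptor")
  res <- function(class, partner_row = NULL, nt = NA_integer_,
                  tx = NA_character_) {
    partner <- if (!is.null(partner_row))
      junction_id(partner_row$chrom, partner_row$intron_start,
                  partner_row$intron_end, partner_row$strand) else NA_character_
    gene <- if (!is.null(partner_row)) partner_row$gene_id else {
      g <- gene_spans(annotation)
      ov <- g$gene_id[g$chrom == chrom & g$start <= intron_start &
                        g$end >= intron_end & g$strand == strand]
      if (length(ov)) ov[1] else "intergenic"
    }
    list(event_class = class, canonical_partner = partner,
         inserted_or_deleted_nt = nt,
         frame_shift = if (is.na(nt)) NA else (nt %% 3L != 0L),
         gene_id = gene,
         transcript_id = if (!is.null(partner_row)) partner_row$transcript_id
         else tx)
  }
  exact <- introns[introns$intron_start == intron_start &
                     introns$intron_end == intron_end, , drop = FALSE]
  if (nrow(exact)) return(res("degenerate", exact[1, ], 0L))
  # exon skip: donor of intron i, acceptor of a 3'-ward intron j of the same
  # transcript; the exons between are removed from the mature transcript
  d_hit <- introns[introns$donor == d, , drop = FALSE]
  a_hit <- introns[introns$acceptor == a, , drop = FALSE]
  if (nrow(d_hit) && nrow(a_hit)) {
    for (tx in intersect(d_hit$transcript_id, a_hit$transcript_id)) {
      i <- d_hit$intron_index[d_hit$transcript_id == tx][1]
      j <- a_hit$intron_index[a_hit$transcript_id == tx][1]
      if (j > i) {
        ex <- annotation$exons[annotation$exons$transcript_id == tx, ,
                               drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
        skipped <- ex[seq(i + 1, j), , drop = FALSE]
        nt <- -sum(skipped$end - skipped$start + 1L)
        return(res("exon skip", d_hit[d_hit$transcript_id == tx, ][1, ], nt))
      }
    }
  }
  if (nrow(d_hit)) {
    p <- d_hit[1, ]
    nt <- (p$intron_end - p$intron_start) - (intron_end - intron_start)
    return(res("alternative 3' acceptor", p, as.integer(nt)))
  }
  if (nrow(a_hit)) {
    p <- a_hit[1, ]
    nt <- (p$intron_end - p$intron_start) - (intron_end - intron_start)
    return(res("alternative 5' donor", p, as.integer(nt)))
  }
  inside <- introns[introns$intron_start < intron_start &
                      introns$intron_end > intron_end, , drop = FALSE]
  if (nrow(inside)) return(res("intron retention proxy", inside[1, ]))
  res("other")
}

# Mature-transcript blocks (genomic, ascending) after applying an optional
# cryptic junction: the intronic sequence the cryptic junction fails to
# remove stays in the transcript, and everything it removes is excised.
mature_blocks <- function(annotation, transcript_id, cryptic = NULL) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, ,
                         drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  ir <- IRanges::IRanges(ex$start, ex$end)
  if (!is.null(cryptic)) {
    xs <- cryptic[1]; xe <- cryptic[2]
    if (nrow(ex) > 1) {
      intr <- IRanges::IRanges(ex$end[-nrow(ex)] + 1L, ex$start[-1] - 1L)
      ov <- IRanges::overlapsAny(intr, IRanges::IRanges(xs, xe))
      if (any(ov)) ir <- IRanges::reduce(c(ir, intr[ov]))
    }
    ir <- IRanges::setdiff(ir, IRanges::IRanges(xs, xe))
  }
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# Transcript coordinate (1-based, 5'->3') of a genomic position within
# mature blocks, or NA if the base is spliced out.
tx_coord <- function(blocks, strand, gpos) {
  widths <- blocks$end - blocks$start + 1L
  if (strand == "+") {
    before <- cumsum(c(0L, widths))[-(nrow(blocks) + 1L)]
    for (i in seq_len(nrow(blocks)))
      if (gpos >= blocks$start[i] && gpos <= blocks$end[i])
        return(before[i] + (gpos - blocks$start[i]) + 1L)
  } else {
    blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
    widths <- rev(widths)
    before <- cumsum(c(0L, widths))[-(nrow(blocks) + 1L)]
    for (i in seq_len(nrow(blocks)))
      if (gpos >= blocks$start[i] && gpos <= blocks$end[i])
        return(before[i] + (blocks$end[i] - gpos) + 1L)
  }
  NA_integer_
}

mature_sequence <- function(annotation, blocks, chrom, strand) {
  if (is.null(annotation$genome) || !chrom %in% names(annotation$genome))
    stop("no genome sequence for chromosome ", chrom)
  seq <- paste(substring(annotation$genome[[chrom]], blocks$start, blocks$end),
               collapse = "")
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

first_stop <- function(seq, from) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  pos <- seq.int(from, n - 2L, by = 3L)
  if (!length(pos)) return(NA_integer_)
  codons <- substring(seq, pos, pos + 2L)
  hit <- which(codons %in% stops)
  if (!length(hit)) return(NA_integer_)
  pos[hit[1]]
}

#' Predict premature termination and nonsense-mediated decay
#'
#' Rebuilds the mature mRNA with the cryptic junction applied, translates
#' from the annotated start codon and reports the first in-frame stop that
#' falls upstream of the canonical stop. NMD is predicted when that PTC lies
#' more than `nmd_rule_nt` nucleotides upstream of the final exon-exon
#' junction of the cryptic transcript (the classical 50-nt rule; threshold
#' configurable).
#'
#' @param annotation a [toy_annotation()] carrying a genome sequence
#' @param transcript_id transcript whose CDS is used
#' @param cryptic c(intron_start, intron_end) of the cryptic junction
#' @param nmd_rule_nt the last-junction distance threshold (default 50)
#' @return list: applicable (FALSE when the event lies outside the CDS or
#'   the start codon is lost), ptc_position (transcript coordinate of the
#'   PTC's first base, NA if none), nmd_predicted (FALSE when no PTC arises,
#'   NA when not applicable), dist_to_last_junction
#' @export
predict_ptc_nmd <- function(annotation, transcript_id, cryptic,
                            nmd_rule_nt = 50L) {
  notapp <- list(applicable = FALSE, ptc_position = NA_integer_,
                 nmd_predicted = NA, dist_to_last_junction = NA_integer_)
  if (is.null(annotation$cds)) return(notapp)
  cd <- annotation$cds[annotation$cds$transcript_id == transcript_id, ,
                       drop = FALSE]
  if (nrow(cd) != 1) return(notapp)
  gene <- annotation$transcripts$gene_id[
    annotation$transcripts$transcript_id == transcript_id]
  strand <- annotation$genes$strand[annotation$genes$gene_id == gene]
  chrom <- annotation$genes$chrom[annotation$genes$gene_id == gene]
  # event outside the CDS span: no PTC call
  if (cryptic[2] < cd$cds_start || cryptic[1] > cd$cds_end) return(notapp)
  blocks <- mature_blocks(annotation, transcript_id, cryptic)
  can_blocks <- mature_blocks(annotation, transcript_id, NULL)
  start_g <- if (strand == "+") cd$cds_start else cd$cds_end
  p0 <- tx_coord(blocks, strand, start_g)
  if (is.na(p0)) return(notapp)
  seq <- mature_sequence(annotation, blocks, chrom, strand)
  stop_pos <- first_stop(seq, p0)
  # canonical stop mapped into the cryptic transcript, via its genomic base
  can_seq <- mature_sequence(annotation, can_blocks, chrom, strand)
  can_p0 <- tx_coord(can_blocks, strand, start_g)
  can_stop_tx <- first_stop(can_seq, can_p0)
  can_stop_g <- NA_integer_
  if (!is.na(can_stop_tx)) {
    # invert the canonical transcript coordinate to genomic
    widths <- can_blocks$end - can_blocks$start + 1L
    bl <- if (strand == "+") can_blocks else
      can_blocks[rev(seq_len(nrow(can_blocks))), , drop = FALSE]
    w <- if (strand == "+") widths else rev(widths)
    cum <- cumsum(w)
    bi <- which(can_stop_tx <= cum)[1]
    off <- can_stop_tx - c(0L, cum)[bi] - 1L
    can_stop_g <- if (strand == "+") bl$start[bi] + off else bl$end[bi] - off
  }
  p_can <- if (!is.na(can_stop_g)) tx_coord(blocks, strand, can_stop_g)
  else NA_integer_
  is_ptc <- !is.na(stop_pos) && (is.na(p_can) || stop_pos < p_can)
  if (!is_ptc)
    return(list(applicable = TRUE, ptc_position = NA_integer_,
                nmd_predicted = FALSE, dist_to_last_junction = NA_integer_))
  widths <- blocks$end - blocks$start + 1L
  last_junction <- if (nrow(blocks) > 1) sum(widths) - widths[
    if (strand == "+") nrow(blocks) else 1L] else NA_integer_
  dist <- if (is.na(last_junction)) NA_integer_ else last_junction - stop_pos
  nmd <- if (is.na(dist)) FALSE else dist > nmd_rule_nt
  list(applicable = TRUE, ptc_position = as.integer(stop_pos),
       nmd_predicted = nmd, dist_to_last_junction = as.integer(dist))
}

#' Hotspot-specificity calls and overlap summary
#'
#' For each junction and each non-reference genotype: `present` when the
#' delta PSI versus the reference reaches `t_present` with at least
#' `min_informative` informative samples; `absent` when the delta is
#' computed and its magnitude is at most `t_absent`; otherwise
#' `indeterminate`. The buffer between the two thresholds makes `absent` an
#' affirmative claim rather than mere non-significance. Labels:
#' `"<G>-specific"` when present in exactly one genotype and absent in all
#' others, `"shared"` when present in two or more, `"ambiguous"` when
#' present in one but not affirmatively absent elsewhere, `"none"`
#' otherwise. The overlap summary reports the Jaccard index of the present
#' sets for every genotype pair.
#'
#' @param results data.frame from [delta_psi()]
#' @param t_present presence threshold on delta PSI (default 0.10)
#' @param t_absent absence threshold on |delta PSI| (default 0.05)
#' @param min_informative minimum informative samples per group (default 2)
#' @return list: `calls` (junction, status_<genotype> columns, label) and
#'   `jaccard` (genotype_a, genotype_b, jaccard, n_a, n_b, n_shared)
#' @export
call_specificity <- function(results, t_present = 0.10, t_absent = 0.05,
                             min_informative = 2L) {
  if (t_absent >= t_present)
    stop("t_absent must be smaller than t_present")
  gts <- sub("^delta_", "", grep("^delta_", names(results), value = TRUE))
  if (length(gts) < 2)
    stop("specificity calls need delta PSI for at least two genotypes")
  calls <- data.frame(junction = results$junction, stringsAsFactors = FALSE)
  status <- matrix("indeterminate", nrow = nrow(results), ncol = length(gts),
                   dimnames = list(NULL, gts))
  for (g in gts) {
    d <- results[[paste0("delta_", g)]]
    n <- results[[paste0("n_", g)]]
    ok <- !is.na(d) & n >= min_informative
    status[ok & d >= t_present, g] <- "present"
    status[ok & abs(d) <= t_absent, g] <- "absent"
  }
  label <- apply(status, 1, function(s) {
    pres <- names(s)[s == "present"]
    if (length(pres) >= 2) return("shared")
    if (length(pres) == 1) {
      if (all(s[setdiff(names(s), pres)] == "absent"))
        return(paste0(pres, "-specific"))
      return("ambiguous")
    }
    "none"
  })
  for (g in gts) calls[[paste0("status_", g)]] <- status[, g]
  calls$label <- label
  jac <- list()
  for (i in seq_len(length(gts) - 1)) for (j in seq(i + 1, length(gts))) {
    a <- calls$junction[status[, gts[i]] == "present"]
    b <- calls$junction[status[, gts[j]] == "present"]
    u <- length(union(a, b))
    jac[[length(jac) + 1L]] <- data.frame(
      genotype_a = gts[i], genotype_b = gts[j],
      jaccard = if (u == 0) 0 else length(intersect(a, b)) / u,
      n_a = length(a), n_b = length(b), n_shared = length(intersect(a, b)),
      stringsAsFactors = FALSE)
  }
  list(calls = calls, jaccard = do.call(rbind, jac))
}

#' Annotate ranked events with class, frame, PTC/NMD and gene
#'
#' Convenience wrapper running [classify_event()] and (where a CDS and
#' genome sequence are available) [predict_ptc_nmd()] over a ranked
#' differential table.
#'
#' @param ranked data.frame from [rank_events()]
#' @param annotation a [toy_annotation()]
#' @param nmd_rule_nt passed to [predict_ptc_nmd()]
#' @return `ranked` with event_class, canonical_partner, gene_id,
#'   inserted_or_deleted_nt, frame_shift, ptc_position, nmd_predicted
#' @export
annotate_events <- function(ranked, annotation, nmd_rule_nt = 50L) {
  coords <- parse_junction_id(ranked$junction)
  cls <- lapply(seq_len(nrow(ranked)), function(i)
    classify_event(coords$chrom[i], coords$intron_start[i],
                   coords$intron_end[i], coords$strand[i], annotation))
  ranked$event_class <- vapply(cls, `[[`, "", "event_class")
  ranked$canonical_partner <- vapply(cls, `[[`, "", "canonical_partner")
  ranked$gene_id <- vapply(cls, `[[`, "", "gene_id")
  ranked$inserted_or_deleted_nt <- vapply(cls, function(x)
    as.integer(x$inserted_or_deleted_nt), integer(1))
  ranked$frame_shift <- vapply(cls, function(x) {
    fs <- x$frame_shift
    if (is.null(fs) || is.na(fs)) NA else fs
  }, logical(1))
  ranked$ptc_position <- NA_integer_
  ranked$nmd_predicted <- NA
  has_seq <- !is.null(annotation$genome)
  for (i in seq_len(nrow(ranked))) {
    tx <- cls[[i]]$transcript_id
    if (has_seq && !is.na(tx) &&
        cls[[i]]$event_class %in% c("alternative 3' acceptor",
                                    "alternative 5' donor", "exon skip")) {
      p <- predict_ptc_nmd(annotation, tx,
                           c(coords$intron_start[i], coords$intron_end[i]),
                           nmd_rule_nt = nmd_rule_nt)
      ranked$ptc_position[i] <- p$ptc_position
      ranked$nmd_predicted[i] <- p$nmd_predicted
    }
  }
  ranked
}

#' Write cryptic junctions as BED for browser inspection
#'
#' @param results data.frame with a `junction` column (and optionally
#'   `score`)
#' @param path output BED file (0-based half-open)
#' @return `path`, invisibly
#' @export
write_events_bed <- function(results, path) {
  coords <- parse_junction_id(results$junction)
  score <- if ("score" %in% names(results))
    pmin(1000L, as.integer(round(1000 * results$score))) else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   coords$chrom, coords$intron_start - 1L, coords$intron_end,
                   results$junction, score, coords$strand)
  writeLines(lines, path)
  invisible(path)
}
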