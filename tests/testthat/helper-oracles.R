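# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

make_jx <- function(chrom, start, end, strand, count, sample) {
  data.frame(chrom = chrom, intron_start = as.integer(start),
             intron_end = as.integer(end), strand = strand,
             unique_count = as.integer(count), sample_id = sample,
             stringsAsFactors = FALSE)
}

jid <- function(chrom, start, end, strand)
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)

# A one-gene annotation with a single intron 1001-2000 on '+': the minimal
# scaffold for donor-anchored cryptic-acceptor cases.
one_intron_annotation <- function(strand = "+") {
  toy_annotation(
    genes = data.frame(gene_id = "g", chrom = "chr1", strand = strand),
    transcripts = data.frame(transcript_id = "g.t", gene_id = "g"),
    exons = data.frame(transcript_id = "g.t",
                       start = c(801L, 2001L), end = c(1000L, 2400L))
  )
}

# all-pairs anchor grouping oracle: a site's group is the set of junctions
# sharing that exact (chrom, position, side, strand); emitted when >= 2
# members or the site is used by an annotated intron
oracle_groups <- function(jx, ann) {
  introns <- annotated_introns(ann)
  jx <- unique(jx[, c("chrom", "intron_start", "intron_end", "strand")])
  site <- function(df, side) {
    pos <- if (side == "donor") ifelse(df$strand == "-", df$intron_end, df$intron_start)
    else ifelse(df$strand == "-", df$intron_start, df$intron_end)
    paste(df$chrom, pos, side, df$strand)
  }
  res <- list()
  for (side in c("donor", "acceptor")) {
    keys <- site(jx, side)
    ann_keys <- site(data.frame(chrom = introns$chrom,
                                intron_start = introns$intron_start,
                                intron_end = introns$intron_end,
                                strand = introns$strand), side)
    for (k in unique(keys)) {
      members <- jid(jx$chrom[keys == k], jx$intron_start[keys == k],
                     jx$intron_end[keys == k], jx$strand[keys == k])
      if (length(members) >= 2 || k %in% ann_keys)
        res[[k]] <- sort(members)
    }
  }
  res
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p-value
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1.0)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-rolled product-limit estimator over distinct event times
oracle_km <- function(times, events) {
  ev_times <- sort(unique(times[events]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# hand-rolled one-degree-of-freedom log-rank statistic
oracle_logrank_chisq <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  grp_a <- c(rep(TRUE, length(ta)), rep(FALSE, length(tb)))
  ev_times <- sort(unique(times[events]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk); na <- sum(at_risk & grp_a)
    d <- sum(times == t & events)
    da <- sum(times == t & events & grp_a)
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact two-sided permutation p for the rank-sum statistic (untied data)
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b); n <- length(x); na <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# directly recompute a PSI matrix cell-for-cell from first principles
oracle_psi <- function(jx, ann, min_coverage) {
  grps <- oracle_groups(jx, ann)
  uniq <- unique(jx[, c("chrom", "intron_start", "intron_end", "strand")])
  ids <- jid(uniq$chrom, uniq$intron_start, uniq$intron_end, uniq$strand)
  introns <- annotated_introns(ann)
  ann_ids <- jid(introns$chrom, introns$intron_start, introns$intron_end,
                 introns$strand)
  samples <- sort(unique(jx$sample_id))
  count_of <- function(id, s) {
    rec <- jx[jid(jx$chrom, jx$intron_start, jx$intron_end, jx$strand) == id &
                jx$sample_id == s, ]
    if (nrow(rec)) sum(rec$unique_count) else 0L
  }
  psi <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
  for (id in ids) {
    mine <- names(grps)[vapply(grps, function(m) id %in% m, logical(1))]
    if (!length(mine)) next
    has_canon <- vapply(grps[mine], function(m) any(m %in% ann_ids), logical(1))
    cand <- if (any(has_canon)) mine[has_canon] else mine
    donor_side <- grepl(" donor ", cand)
    pick <- if (any(donor_side)) cand[donor_side][1] else cand[1]
    members <- grps[[pick]]
    for (s in samples) {
      tot <- sum(vapply(members, count_of, numeric(1), s = s))
      psi[id, s] <- if (tot >= min_coverage) count_of(id, s) / tot else NA_real_
    }
  }
  psi
}

# synthetic cohort reproducing the printed variant-by-diagnosis counts
printed_partition_cohort <- function() {
  counts <- rbind(
    data.frame(variant = "K666N", diagnosis = c("MDS-RS", "MDS-SLD/MLD", "MDS-EB", "AML"),
               n = c(28, 21, 46, 103)),
    data.frame(variant = "E592K", diagnosis = c("MDS-RS", "MDS-SLD/MLD", "MDS-EB", "AML"),
               n = c(1, 9, 9, 10)),
    data.frame(variant = "E622D", diagnosis = c("MDS-RS", "MDS-SLD/MLD", "MDS-EB", "AML"),
               n = c(92, 7, 1, 2)),
    data.frame(variant = "K666R", diagnosis = c("MDS-RS", "MDS-SLD/MLD", "MDS-EB", "AML"),
               n = c(72, 3, 3, 7))
  )
  totals <- c("MDS-RS" = 1327, "MDS-SLD/MLD" = 242, "MDS-EB" = 266, "AML" = 399)
  rows <- list()
  for (i in seq_len(nrow(counts)))
    rows[[i]] <- data.frame(diagnosis = counts$diagnosis[i],
                            sf3b1_variant = rep(counts$variant[i], counts$n[i]))
  for (d in names(totals)) {
    rest <- totals[[d]] - sum(counts$n[counts$diagnosis == d])
    rows[[length(rows) + 1L]] <- data.frame(diagnosis = d,
                                            sf3b1_variant = rep("K700E", rest))
  }
  out <- do.call(rbind, rows)
  out$case_id <- sprintf("p%04d", seq_len(nrow(out)))
  out
}
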