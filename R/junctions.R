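#' Read a splice-junction count table
#'
#' Supported dialects:
#' \describe{
#'   \item{`"star"`}{STAR `SJ.out.tab`: 9 tab-separated columns — chrom,
#'     intron start, intron end (1-based inclusive), strand code
#'     (0 = unknown, 1 = '+', 2 = '-'), intron motif, annotated flag,
#'     unique-mapping split-read count, multi-mapping count, max overhang.
#'     Only the unique-mapping count is used.}
#'   \item{`"bed"`}{6-column BED of introns (0-based half-open), score column
#'     holding the unique split-read count; converted to 1-based inclusive on
#'     ingest.}
#' }
#' Comment lines starting with `#` are skipped.
#'
#' @param path file to read
#' @param sample_id sample label attached to every record; defaults to the
#'   file name without extension
#' @param dialect `"star"` or `"bed"`
#' @return data.frame of junction records: chrom, intron_start, intron_end,
#'   strand ('+', '-' or '*' for unknown), unique_count, sample_id
#' @export
read_junction_table <- function(path, sample_id = NULL,
                                dialect = c("star", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction table not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(raw)]
  if (!length(raw)) return(empty_junctions(sample_id))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncol_needed <- if (dialect == "star") 9L else 6L
  nf <- vapply(fields, length, integer(1))
  if (any(nf != ncol_needed)) {
    bad <- which(nf != ncol_needed)[1]
    stop(sprintf("%s: line %d has %d columns, expected %d",
                 path, bad, nf[bad], ncol_needed))
  }
  m <- do.call(rbind, fields)
  if (dialect == "star") {
    code <- as.integer(m[, 4])
    if (any(is.na(code)) || any(!code %in% 0:2))
      stop(path, ": unknown strand code; expected 0/1/2")
    out <- data.frame(
      chrom = m[, 1],
      intron_start = as.integer(m[, 2]),
      intron_end = as.integer(m[, 3]),
      strand = c("*", "+", "-")[code + 1L],
      unique_count = as.integer(m[, 7]),
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      chrom = m[, 1],
      intron_start = as.integer(m[, 2]) + 1L,  # 0-based half-open -> 1-based
      intron_end = as.integer(m[, 3]),
      strand = m[, 6],
      unique_count = as.integer(m[, 5]),
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
    if (any(!out$strand %in% c("+", "-", ".", "*")))
      stop(path, ": unknown BED strand")
    out$strand[out$strand == "."] <- "*"
  }
  if (any(out$unique_count < 0, na.rm = TRUE))
    stop(path, ": negative split-read count")
  if (any(out$intron_start >= out$intron_end))
    stop(path, ": intron start must be < intron end")
  out
}

empty_junctions <- function(sample_id = character()) {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             unique_count = integer(),
             sample_id = if (length(sample_id)) character() else character(),
             stringsAsFactors = FALSE)
}

#' Group junctions at shared donor/acceptor anchor sites
#'
#' Junctions are keyed by their strand-aware donor site (5' end of the
#' intron) and acceptor site (3' end). A group is emitted for every site
#' shared by two or more distinct junctions, and for a site used by a single
#' junction when that site belongs to an annotated intron. The member that
#' exactly matches an annotated intron is flagged canonical.
#'
#' Junctions with unknown strand inherit the strand of the annotated gene
#' whose span contains them; junctions that remain ambiguous are dropped with
#' a warning. A strand contradiction between table and annotation is an
#' error.
#'
#' @param junctions data.frame as from [read_junction_table()] (the
#'   `sample_id`/`unique_count` columns are ignored here; grouping uses the
#'   distinct junction coordinates)
#' @param annotation a [toy_annotation()]
#' @return data.frame with one row per (group, member): group_id, chrom,
#'   anchor_pos, side ('donor'/'acceptor'), strand, junction (id string),
#'   is_canonical, annotated (junction matches an annotated intron),
#'   gene_id of the anchor's annotated intron when known
#' @export
build_anchor_groups <- function(junctions, annotation) {
  ann_introns <- annotated_introns(annotation)
  jx <- unique(junctions[, c("chrom", "intron_start", "intron_end", "strand")])
  if (!nrow(jx)) return(empty_groups())

  # resolve unknown strands from the annotation
  ann_key <- paste(ann_introns$chrom, ann_introns$intron_start,
                   ann_introns$intron_end)
  jx_key <- paste(jx$chrom, jx$intron_start, jx$intron_end)
  hit <- match(jx_key, ann_key)
  contradict <- !is.na(hit) & jx$strand != "*" &
    jx$strand != ann_introns$strand[hit]
  if (any(contradict))
    stop("strand contradicts annotation for junction(s): ",
         paste(junction_id(jx$chrom[contradict], jx$intron_start[contradict],
                           jx$intron_end[contradict], jx$strand[contradict]),
               collapse = ", "))
  unk <- jx$strand == "*"
  if (any(unk)) {
    for (i in which(unk)) {
      g <- gene_spans(annotation)
      ov <- g[g$chrom == jx$chrom[i] & g$start <= jx$intron_start[i] &
                g$end >= jx$intron_end[i], , drop = FALSE]
      s <- unique(ov$strand)
      if (length(s) == 1) jx$strand[i] <- s
    }
    still <- jx$strand == "*"
    if (any(still)) {
      warning(sum(still), " junction(s) with unresolvable strand excluded")
      jx <- jx[!still, , drop = FALSE]
      if (!nrow(jx)) return(empty_groups())
    }
  }

  jx$junction <- junction_id(jx$chrom, jx$intron_start, jx$intron_end, jx$strand)
  jx$annotated <- paste(jx$chrom, jx$intron_start, jx$intron_end, jx$strand) %in%
    paste(ann_introns$chrom, ann_introns$intron_start, ann_introns$intron_end,
          ann_introns$strand)

  rows <- list()
  for (side in c("donor", "acceptor")) {
    pos <- anchor_pos(jx$intron_start, jx$intron_end, jx$strand, side)
    key <- paste(jx$chrom, pos, side, jx$strand)
    ann_pos <- if (side == "donor") ann_introns$donor else ann_introns$acceptor
    ann_site_key <- paste(ann_introns$chrom, ann_pos, side, ann_introns$strand)
    for (k in unique(key)) {
      idx <- which(key == k)
      site_annotated <- k %in% ann_site_key
      if (length(idx) >= 2 || (length(idx) == 1 && site_annotated)) {
        gene <- NA_character_
        if (site_annotated)
          gene <- ann_introns$gene_id[match(k, ann_site_key)]
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = k,
          chrom = jx$chrom[idx][1],
          anchor_pos = pos[idx][1],
          side = side,
          strand = jx$strand[idx][1],
          junction = jx$junction[idx],
          is_canonical = jx$annotated[idx],
          annotated = jx$annotated[idx],
          gene_id = gene,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty_groups())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gene_spans <- function(annotation) {
  tx2gene <- stats::setNames(annotation$transcripts$gene_id,
                             annotation$transcripts$transcript_id)
  ex <- annotation$exons
  ex$gene_id <- tx2gene[ex$transcript_id]
  ids <- unique(ex$gene_id)
  data.frame(
    gene_id = ids,
    start = vapply(ids, function(g) min(ex$start[ex$gene_id == g]), numeric(1)),
    end = vapply(ids, function(g) max(ex$end[ex$gene_id == g]), numeric(1)),
    chrom = annotation$genes$chrom[match(ids, annotation$genes$gene_id)],
    strand = annotation$genes$strand[match(ids, annotation$genes$gene_id)],
    stringsAsFactors = FALSE
  )
}

empty_groups <- function() {
  data.frame(group_id = character(), chrom = character(),
             anchor_pos = integer(), side = character(), strand = character(),
             junction = character(), is_canonical = logical(),
             annotated = logical(), gene_id = character(),
             stringsAsFactors = FALSE)
}

#' Quantification configuration
#'
#' @param min_coverage minimum total split-read count at an anchor group in a
#'   sample for PSI to be reported there (default 15, the coverage filter of
#'   the quantification)
#' @param min_samples_per_group minimum number of informative (non-missing)
#'   samples per genotype for a junction to enter differential comparisons
#' @return a list of class `quant_config`
#' @export
quant_config <- function(min_coverage = 15L, min_samples_per_group = 2L) {
  stopifnot(min_coverage >= 1, min_samples_per_group >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_samples_per_group = as.integer(min_samples_per_group)),
            class = "quant_config")
}

# Assign each junction to the single anchor group where its PSI is
# quantified: prefer a group containing a canonical member; among those (or
# failing that, among all its groups) prefer the donor side.
assign_anchor <- function(groups) {
  out <- character(0)
  for (j in unique(groups$junction)) {
    g <- groups[groups$junction == j, , drop = FALSE]
    has_canon <- vapply(g$group_id, function(id)
      any(groups$is_canonical[groups$group_id == id]), logical(1))
    cand <- if (any(has_canon)) g[has_canon, , drop = FALSE] else g
    pick <- if (any(cand$side == "donor"))
      cand$group_id[cand$side == "donor"][1] else cand$group_id[1]
    out[j] <- pick
  }
  out
}

#' Compute the PSI matrix
#'
#' PSI of junction j in sample s is its unique split-read count divided by
#' the total split-read count of all junctions sharing j's anchor group. If
#' that total is below `min_coverage`, PSI is missing (NA) for every member
#' of the group in that sample. Each junction is quantified at exactly one
#' anchor group (see [build_anchor_groups()] and the assignment rule:
#' canonical-containing group preferred, donor side on ties).
#'
#' @param groups output of [build_anchor_groups()]
#' @param junctions long data.frame of junction records across samples
#' @param config a [quant_config()]
#' @param per_group if TRUE, also return the long per-(group, member, sample)
#'   table used for normalization checks
#' @return list of class `psi_matrix`: `psi` (junction x sample matrix, NA =
#'   filtered), `coverage` (anchor-group totals per junction x sample),
#'   `anchor` (named vector junction -> group_id), `groups`, and optionally
#'   `detail`
#' @export
compute_psi <- function(groups, junctions, config = quant_config(),
                        per_group = FALSE) {
  if (!nrow(groups)) stop("no anchor groups supplied")
  samples <- sort(unique(junctions$sample_id))
  jx_all <- unique(groups$junction)
  # counts matrix: junction x sample, absent records count as 0
  jid <- junction_id(junctions$chrom, junctions$intron_start,
                     junctions$intron_end, junctions$strand)
  # unknown-strand records match groups through either strand resolution
  counts <- matrix(0L, nrow = length(jx_all), ncol = length(samples),
                   dimnames = list(jx_all, samples))
  keep <- jid %in% jx_all
  if (any(!keep)) {
    # records whose strand was resolved during grouping: retry with both strands
    unres <- junctions[!keep, , drop = FALSE]
    for (s in c("+", "-")) {
      alt <- junction_id(unres$chrom, unres$intron_start, unres$intron_end, s)
      ok <- alt %in% jx_all & unres$strand == "*"
      if (any(ok))
        for (i in which(ok))
          counts[alt[i], unres$sample_id[i]] <-
            counts[alt[i], unres$sample_id[i]] + unres$unique_count[i]
    }
  }
  for (i in which(keep))
    counts[jid[i], junctions$sample_id[i]] <-
      counts[jid[i], junctions$sample_id[i]] + junctions$unique_count[i]

  anchor <- assign_anchor(groups)
  psi <- matrix(NA_real_, nrow = length(jx_all), ncol = length(samples),
                dimnames = list(jx_all, samples))
  coverage <- matrix(NA_integer_, nrow = length(jx_all), ncol = length(samples),
                     dimnames = list(jx_all, samples))
  detail <- if (per_group) list() else NULL
  for (gid in unique(groups$group_id)) {
    members <- groups$junction[groups$group_id == gid]
    if (!length(members)) stop("internal error: empty anchor group ", gid)
    tot <- colSums(counts[members, , drop = FALSE])
    g_psi <- sweep(counts[members, , drop = FALSE], 2, tot, "/")
    low <- tot < config$min_coverage
    g_psi[, low] <- NA_real_
    assigned <- members[anchor[members] == gid]
    if (length(assigned)) {
      psi[assigned, ] <- g_psi[assigned, , drop = FALSE]
      coverage[assigned, ] <- matrix(rep(as.integer(tot), each = length(assigned)),
                                     nrow = length(assigned))
    }
    if (per_group) {
      detail[[gid]] <- data.frame(
        group_id = gid,
        junction = rep(members, times = length(samples)),
        sample_id = rep(samples, each = length(members)),
        psi = as.vector(g_psi),
        total = rep(as.integer(tot), each = length(members)),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(psi = psi, coverage = coverage, anchor = anchor,
                 groups = groups, config = config,
                 detail = if (per_group) do.call(rbind, detail) else NULL),
            class = "psi_matrix")
}

#' Serialize a PSI matrix as TSV (missing cells written as "NA")
#'
#' @param x a `psi_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_psi_matrix <- function(x, path) {
  df <- data.frame(junction = rownames(x$psi), x$psi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
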