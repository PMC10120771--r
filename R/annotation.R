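#' Construct a toy transcript annotation
#'
#' A minimal gene-model container: genes with chromosome and strand,
#' transcripts made of ordered exons (1-based inclusive genomic intervals)
#' and an optional CDS span per transcript. Optionally carries a genome
#' sequence (named character vector, one element per chromosome) so that
#' mature transcripts can be rebuilt and translated.
#'
#' @param genes data.frame with columns gene_id, chrom, strand ('+'/'-')
#' @param transcripts data.frame with columns transcript_id, gene_id
#' @param exons data.frame with columns transcript_id, start, end
#' @param cds optional data.frame with columns transcript_id, cds_start,
#'   cds_end (genomic span of the coding region, stop codon included)
#' @param genome optional named character vector of chromosome sequences
#' @return an object of class `toy_annotation`
#' @export
toy_annotation <- function(genes, transcripts, exons, cds = NULL, genome = NULL) {
  genes <- as.data.frame(genes)
  transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  stopifnot(
    all(c("gene_id", "chrom", "strand") %in% names(genes)),
    all(c("transcript_id", "gene_id") %in% names(transcripts)),
    all(c("transcript_id", "start", "end") %in% names(exons))
  )
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)
    stopifnot(all(c("transcript_id", "cds_start", "cds_end") %in% names(cds)))
  }
  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         cds = cds, genome = genome),
    class = "toy_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  for (tx in unique(ann$exons$transcript_id)) {
    ex <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$end < ex$start))
      stop("exon with end < start in transcript ", tx)
    if (nrow(ex) > 1) {
      gaps <- ex$start[-1] - ex$end[-nrow(ex)] - 1L
      if (any(gaps < 4L))
        stop("intron shorter than 4 nt (or overlapping exons) in transcript ", tx)
    }
    if (!is.null(ann$cds)) {
      cd <- ann$cds[ann$cds$transcript_id == tx, , drop = FALSE]
      if (nrow(cd) == 1) {
        covered <- any(ex$start <= cd$cds_start & ex$end >= cd$cds_start) &&
          any(ex$start <= cd$cds_end & ex$end >= cd$cds_end)
        if (!covered || cd$cds_start > cd$cds_end)
          stop("CDS span outside the exon union in transcript ", tx)
      }
    }
  }
  invisible(ann)
}

#' Annotated introns of a toy annotation
#'
#' One row per gap between consecutive exons of each transcript, in genomic
#' coordinates (1-based inclusive positions of the first and last intronic
#' base), with the owning gene, strand, and the strand-aware donor and
#' acceptor positions.
#'
#' @param ann a [toy_annotation()]
#' @return data.frame with columns transcript_id, gene_id, chrom, strand,
#'   intron_start, intron_end, donor, acceptor, intron_index (5' to 3')
#' @export
annotated_introns <- function(ann) {
  out <- list()
  tx_gene <- stats::setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  gene_row <- ann$genes[match(tx_gene, ann$genes$gene_id), , drop = FALSE]
  for (i in seq_along(tx_gene)) {
    tx <- names(tx_gene)[i]
    ex <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    strand <- gene_row$strand[i]
    st <- ex$end[-nrow(ex)] + 1L
    en <- ex$start[-1] - 1L
    idx <- seq_along(st)
    if (strand == "-") idx <- rev(idx)
    out[[tx]] <- data.frame(
      transcript_id = tx, gene_id = unname(tx_gene[i]),
      chrom = gene_row$chrom[i], strand = strand,
      intron_start = st, intron_end = en,
      donor = anchor_pos(st, en, strand, "donor"),
      acceptor = anchor_pos(st, en, strand, "acceptor"),
      intron_index = idx,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      donor = integer(), acceptor = integer(),
                      intron_index = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a toy annotation to GTF
#'
#' Emits gene, transcript, exon and CDS features with `gene_id` and
#' `transcript_id` attributes. A comment header records the provenance seed
#' when one is supplied.
#'
#' @param ann a [toy_annotation()]
#' @param path output file
#' @param seed optional integer stamped into the header comment
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path, seed = NULL) {
  lines <- c("##gff-version 2",
             sprintf("#cryptsplice toy annotation%s",
                     if (!is.null(seed)) sprintf(" seed=%d", as.integer(seed)) else ""))
  attr_str <- function(gid, tid = NULL) {
    s <- sprintf('gene_id "%s";', gid)
    if (!is.null(tid)) s <- paste(s, sprintf('transcript_id "%s";', tid))
    s
  }
  feat <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, as.integer(start), as.integer(end), strand, attrs)
  }
  for (g in seq_len(nrow(ann$genes))) {
    grow <- ann$genes[g, ]
    txs <- ann$transcripts[ann$transcripts$gene_id == grow$gene_id, , drop = FALSE]
    gex <- ann$exons[ann$exons$transcript_id %in% txs$transcript_id, , drop = FALSE]
    lines <- c(lines, feat(grow$chrom, "cryptsplice", "gene",
                           min(gex$start), max(gex$end), grow$strand,
                           attr_str(grow$gene_id)))
    for (t in txs$transcript_id) {
      ex <- ann$exons[ann$exons$transcript_id == t, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      lines <- c(lines, feat(grow$chrom, "cryptsplice", "transcript",
                             min(ex$start), max(ex$end), grow$strand,
                             attr_str(grow$gene_id, t)))
      for (e in seq_len(nrow(ex)))
        lines <- c(lines, feat(grow$chrom, "cryptsplice", "exon",
                               ex$start[e], ex$end[e], grow$strand,
                               attr_str(grow$gene_id, t)))
      if (!is.null(ann$cds)) {
        cd <- ann$cds[ann$cds$transcript_id == t, , drop = FALSE]
        if (nrow(cd) == 1) {
          # CDS features clipped to exons
          for (e in seq_len(nrow(ex))) {
            cs <- max(ex$start[e], cd$cds_start)
            ce <- min(ex$end[e], cd$cds_end)
            if (cs <= ce)
              lines <- c(lines, feat(grow$chrom, "cryptsplice", "CDS",
                                     cs, ce, grow$strand,
                                     attr_str(grow$gene_id, t)))
          }
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into a toy annotation
#'
#' Uses rtracklayer's GTF importer and reassembles the exon/CDS structure.
#' The genome sequence is not stored in GTF; pass it separately if
#' translation is needed downstream.
#'
#' @param path GTF file with exon (and optionally CDS) features carrying
#'   `gene_id`/`transcript_id` attributes
#' @param genome optional named character vector of chromosome sequences
#' @return a [toy_annotation()]
#' @export
read_gtf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("no exon features in ", path)
  tx2gene <- unique(ex[, c("transcript_id", "gene_id")])
  tx2chr <- unique(ex[, c("gene_id", "seqnames", "strand")])
  genes <- data.frame(gene_id = as.character(tx2chr$gene_id),
                      chrom = as.character(tx2chr$seqnames),
                      strand = as.character(tx2chr$strand),
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = as.character(tx2gene$transcript_id),
                            gene_id = as.character(tx2gene$gene_id),
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = as.character(ex$transcript_id),
                      start = as.integer(ex$start), end = as.integer(ex$end),
                      stringsAsFactors = FALSE)
  cds <- NULL
  cd <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cd)) {
    agg <- stats::aggregate(cbind(cds_start = start, cds_end = end) ~ transcript_id,
                            data = transform(cd, transcript_id = as.character(transcript_id)),
                            FUN = function(x) x)
    cds <- data.frame(
      transcript_id = agg$transcript_id,
      cds_start = vapply(seq_len(nrow(agg)), function(i) min(cd$start[as.character(cd$transcript_id) == agg$transcript_id[i]]), numeric(1)),
      cds_end = vapply(seq_len(nrow(agg)), function(i) max(cd$end[as.character(cd$transcript_id) == agg$transcript_id[i]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  toy_annotation(genes, transcripts, exons, cds = cds, genome = genome)
}

#' Built-in two-gene toy annotation with genome sequence
#'
#' A compact hand-built annotation used in examples and the shipped
#' pipeline fixture: two plus-strand three-exon genes with clean ORFs
#' (no internal stop codons) and GT..AG introns, so cryptic acceptors
#' shifted into an intron produce well-defined frame and PTC outcomes.
#'
#' @return a [toy_annotation()] carrying a `genome` sequence
#' @export
example_annotation <- function() {
  # coding sequence built from stop-free codons; every exonic coding piece
  # is a whole number of codons so the canonical ORF has no internal stop
  clean_codons <- function(n) paste(rep(c("GCT", "GAA", "CTG", "AAA", "GAC"),
                                        length.out = n), collapse = "")
  set_seq <- function(seq, start, s) {
    substr(seq, start, start + nchar(s) - 1L) <- s
    seq
  }
  chr <- paste(rep("C", 1500), collapse = "")
  # gene G1 ('+'): exons 101-220 / 301-420 / 501-640, CDS 131-560
  # coding pieces: 90 + 120 + 57 nt + TAA
  chr <- set_seq(chr, 131, paste0("ATG", clean_codons(29)))
  chr <- set_seq(chr, 221, "GT"); chr <- set_seq(chr, 299, "AG")
  chr <- set_seq(chr, 301, clean_codons(40))
  # intron2 interior G/C only: a cryptic acceptor there inserts stop-free nt
  chr <- set_seq(chr, 421, paste0("GT", paste(rep("GC", 38), collapse = ""), "AG"))
  chr <- set_seq(chr, 501, paste0(clean_codons(19), "TAA"))
  # gene G2 ('+'): exons 901-1000 / 1101-1199 / 1301-1400, CDS 923-1339
  # coding pieces: 78 + 99 + 36 nt + TAA
  chr <- set_seq(chr, 923, paste0("ATG", clean_codons(25)))
  chr <- set_seq(chr, 1001, "GT"); chr <- set_seq(chr, 1099, "AG")
  chr <- set_seq(chr, 1101, clean_codons(33))
  chr <- set_seq(chr, 1200, "GT"); chr <- set_seq(chr, 1299, "AG")
  chr <- set_seq(chr, 1301, paste0(clean_codons(12), "TAA"))
  toy_annotation(
    genes = data.frame(gene_id = c("G1", "G2"), chrom = "chrT",
                       strand = c("+", "+")),
    transcripts = data.frame(transcript_id = c("G1.t1", "G2.t1"),
                             gene_id = c("G1", "G2")),
    exons = data.frame(
      transcript_id = rep(c("G1.t1", "G2.t1"), each = 3),
      start = c(101L, 301L, 501L, 901L, 1101L, 1301L),
      end = c(220L, 420L, 640L, 1000L, 1199L, 1400L)
    ),
    cds = data.frame(transcript_id = c("G1.t1", "G2.t1"),
                     cds_start = c(131L, 923L), cds_end = c(560L, 1339L)),
    genome = c(chrT = chr)
  )
}

#' Deterministic multi-gene toy annotation
#'
#' Tiles `n_genes` copies of a three-exon gene along one chromosome, giving
#' `2 * n_genes` annotated introns to plant cryptic events into. No genome
#' sequence is attached (junction-level analyses do not need one).
#'
#' @param n_genes number of genes to tile
#' @return a [toy_annotation()]
#' @export
tiled_annotation <- function(n_genes = 20L) {
  stopifnot(n_genes >= 1)
  offs <- 2000L * (seq_len(n_genes) - 1L)
  genes <- data.frame(gene_id = sprintf("SG%02d", seq_len(n_genes)),
                      chrom = "chrS", strand = "+",
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                            gene_id = genes$gene_id,
                            stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = rep(transcripts$transcript_id, each = 3),
    start = as.integer(rep(offs, each = 3) + c(101L, 301L, 501L)),
    end = as.integer(rep(offs, each = 3) + c(220L, 420L, 640L))
  )
  toy_annotation(genes, transcripts, exons)
}
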