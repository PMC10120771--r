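#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed clinical percentages use
#' conventional half-up rounding (e.g. 0.25 -> 0.3 at one decimal).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage the way the cohort tables print it
#'
#' One decimal place by default; two decimals when the value is positive but
#' below 0.1% so that rare variants do not print as "0.0%".
#'
#' @param x percentage on the 0-100 scale
#' @return character vector at the printing precision (half-up rounding),
#'   NA for NA input
#' @export
format_percent <- function(x) {
  digits <- ifelse(!is.na(x) & x > 0 & x < 0.1, 2L, 1L)
  out <- sprintf("%.*f", digits, round_half_up(x, digits))
  out[is.na(x)] <- NA_character_
  out
}

# Stable junction identity string used as a key throughout the package.
junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

parse_junction_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+):([-+.*])$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed junction id: ", paste(id[bad], collapse = ", "))
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    intron_start = as.integer(vapply(m, `[`, "", 3L)),
    intron_end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# Donor/acceptor genomic coordinate of an intron, strand-aware:
# donor = 5' end of the intron (intron_start on '+', intron_end on '-').
anchor_pos <- function(start, end, strand, side) {
  stopifnot(side %in% c("donor", "acceptor"))
  minus <- rep_len(strand == "-", length(start))
  if (side == "donor") ifelse(minus, end, start)
  else ifelse(minus, start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
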