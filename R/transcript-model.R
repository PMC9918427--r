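#' Construct a transcript model
#'
#' A transcript model carries the exon structure of a (possibly minus-strand)
#' multi-exon transcript, the CDS boundaries in transcript coordinates, and
#' optionally the genomic sequence spanning the locus, so that splice events
#' can be applied and translated. Genomic intervals are 1-based inclusive and
#' always stored with `start <= end`; transcript order for a minus-strand gene
#' runs along decreasing genomic coordinates (as for USH2A).
#'
#' @param id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of genomic exon boundaries in
#'   transcript order (rank 1 = 5' end of the transcript).
#' @param cds_start_c,cds_end_c CDS boundaries in transcript coordinates
#'   (1 = first transcribed nucleotide); the CDS length must be a multiple
#'   of 3.
#' @param genome_seq optional character string or [Biostrings::DNAString] with
#'   the plus-strand genomic sequence covering all exons and introns.
#' @param genome_start genomic coordinate of the first base of `genome_seq`.
#' @param assembly assembly label (default `"hg19"`).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exon_starts, exon_ends,
                             cds_start_c, cds_end_c,
                             genome_seq = NULL, genome_start = 1L,
                             assembly = "hg19") {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  strand <- match.arg(strand, c("+", "-"))
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_starts > exon_ends))
    stop("exon start greater than end; genomic intervals must have start <= end")
  # transcript order check: "+" ascending, "-" descending along rank
  if (length(exon_starts) > 1) {
    gaps_ok <- if (strand == "+")
      all(diff(exon_starts) > 0) && all(exon_starts[-1] > exon_ends[-length(exon_ends)])
    else
      all(diff(exon_starts) < 0) && all(exon_ends[-1] < exon_starts[-length(exon_starts)])
    if (!gaps_ok)
      stop("exons must be non-overlapping and sorted in transcript order for strand ", strand)
  }
  exon_len <- exon_ends - exon_starts + 1L
  tx_len <- sum(exon_len)
  cds_start_c <- as.integer(cds_start_c)
  cds_end_c <- as.integer(cds_end_c)
  if (cds_start_c < 1 || cds_end_c > tx_len || cds_start_c >= cds_end_c)
    stop("CDS boundaries outside transcript")
  if ((cds_end_c - cds_start_c + 1L) %% 3L != 0L)
    stop("CDS length is not divisible by 3")
  if (!is.null(genome_seq)) {
    genome_seq <- toupper(as.character(genome_seq))
    lo <- min(exon_starts); hi <- max(exon_ends)
    if (genome_start > lo || genome_start + nchar(genome_seq) - 1L < hi)
      stop("genome_seq does not cover the exon span")
  }
  structure(list(
    id = id, chrom = chrom, strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    exon_lengths = exon_len,
    cum_before = c(0L, cumsum(exon_len))[seq_along(exon_len)],
    tx_length = tx_len,
    cds_start_c = cds_start_c, cds_end_c = cds_end_c,
    genome_seq = genome_seq, genome_start = as.integer(genome_start),
    assembly = assembly
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, strand %s, %d exons, %d nt, CDS %d..%d)\n",
              x$id, x$chrom, x$strand, length(x$exon_starts), x$tx_length,
              x$cds_start_c, x$cds_end_c))
  invisible(x)
}

#' Number of exons in a transcript model
#' @param tx a `transcript_model`.
#' @return integer exon count.
#' @export
n_exons <- function(tx) length(tx$exon_starts)

# transcript position (1..tx_length) -> genomic position
t_to_g <- function(tx, t_pos) {
  t_pos <- as.integer(t_pos)
  if (any(t_pos < 1L | t_pos > tx$tx_length))
    stop("transcript position outside transcript")
  k <- vapply(t_pos, function(p) which(p > tx$cum_before &
                                         p <= tx$cum_before + tx$exon_lengths)[1], 1L)
  off <- t_pos - tx$cum_before[k] - 1L
  if (tx$strand == "+") tx$exon_starts[k] + off else tx$exon_ends[k] - off
}

# genomic position -> transcript position (NA if intronic/outside)
g_to_t <- function(tx, g_pos) {
  g_pos <- as.integer(g_pos)
  vapply(g_pos, function(g) {
    k <- which(g >= tx$exon_starts & g <= tx$exon_ends)
    if (length(k) == 0) return(NA_integer_)
    k <- k[1]
    off <- if (tx$strand == "+") g - tx$exon_starts[k] else tx$exon_ends[k] - g
    tx$cum_before[k] + off + 1L
  }, 1L)
}

# cDNA (HGVS c.) position -> transcript position.
# pos > 0: coding/3'-side counting from CDS start; pos < 0: 5' UTR; star: 3' UTR.
c_to_t <- function(tx, pos, star = FALSE) {
  pos <- as.integer(pos)
  if (star) {
    if (pos < 1) stop("3' UTR (*) position must be >= 1")
    t_pos <- tx$cds_end_c + pos
  } else if (pos > 0) {
    t_pos <- tx$cds_start_c + pos - 1L
  } else if (pos < 0) {
    t_pos <- tx$cds_start_c + pos
  } else stop("cDNA position 0 does not exist")
  if (t_pos < 1L || t_pos > tx$tx_length)
    stop("cDNA position ", pos, " outside transcript")
  t_pos
}

t_to_c <- function(tx, t_pos) {
  if (t_pos < tx$cds_start_c)
    list(pos = t_pos - tx$cds_start_c, star = FALSE)
  else if (t_pos > tx$cds_end_c)
    list(pos = t_pos - tx$cds_end_c, star = TRUE)
  else
    list(pos = t_pos - tx$cds_start_c + 1L, star = FALSE)
}

#' Map a cDNA position (with optional intronic offset) to a genomic position
#'
#' Implements HGVS c.-style coordinates: positive positions count from the
#' first base of the start codon, negative positions are 5' UTR, and an
#' intronic offset (`c.4397-3890` has position 4397, offset -3890) walks from
#' an exon boundary into the adjacent intron. On a minus-strand transcript,
#' increasing cDNA positions map to decreasing genomic positions.
#'
#' @param tx a [transcript_model].
#' @param pos cDNA anchor position (integer; negative for 5' UTR).
#' @param offset intronic offset (0 for exonic positions). A positive offset
#'   requires the anchor to be the last base of an exon (donor side), a
#'   negative offset the first base of an exon (acceptor side), and the offset
#'   must stay within the adjacent intron.
#' @param star logical; `TRUE` for 3' UTR (`*`) positions.
#' @return integer genomic position.
#' @export
c_to_genomic <- function(tx, pos, offset = 0L, star = FALSE) {
  t_pos <- c_to_t(tx, pos, star = star)
  g <- t_to_g(tx, t_pos)
  offset <- as.integer(offset)
  if (offset == 0L) return(g)
  k <- which(t_pos > tx$cum_before & t_pos <= tx$cum_before + tx$exon_lengths)[1]
  if (offset > 0L) {
    if (t_pos != tx$cum_before[k] + tx$exon_lengths[k])
      stop("positive intronic offset anchored to a non-boundary position")
    if (k == n_exons(tx)) stop("no intron downstream of the last exon")
    intron_len <- abs(if (tx$strand == "+")
      tx$exon_starts[k + 1] - tx$exon_ends[k] else tx$exon_starts[k] - tx$exon_ends[k + 1]) - 1L
    if (offset > intron_len)
      stop("offset ", offset, " walks past the neighbouring exon (intron length ",
           intron_len, ")")
  } else {
    if (t_pos != tx$cum_before[k] + 1L)
      stop("negative intronic offset anchored to a non-boundary position")
    if (k == 1L) stop("no intron upstream of the first exon")
    intron_len <- abs(if (tx$strand == "+")
      tx$exon_starts[k] - tx$exon_ends[k - 1] else tx$exon_starts[k - 1] - tx$exon_ends[k]) - 1L
    if (-offset > intron_len)
      stop("offset ", offset, " walks past the neighbouring exon (intron length ",
           intron_len, ")")
  }
  if (tx$strand == "+") g + offset else g - offset
}

#' Map a genomic position to a cDNA position with intronic offset
#'
#' Inverse of [c_to_genomic()]. Intronic positions are anchored to the nearer
#' exon boundary (HGVS convention); at the exact midpoint of an intron the
#' donor (`+`) side of the upstream exon is used.
#'
#' @param tx a [transcript_model].
#' @param g_pos integer genomic position within the transcript span.
#' @return a list with elements `pos`, `offset`, `star`.
#' @export
genomic_to_c <- function(tx, g_pos) {
  g_pos <- as.integer(g_pos)
  t_pos <- g_to_t(tx, g_pos)
  if (!is.na(t_pos)) {
    out <- t_to_c(tx, t_pos)
    return(list(pos = out$pos, offset = 0L, star = out$star))
  }
  lo <- min(tx$exon_starts); hi <- max(tx$exon_ends)
  if (g_pos < lo || g_pos > hi) stop("genomic position outside the transcript span")
  # locate the flanking exons (in transcript order) of the intron containing g_pos
  for (k in seq_len(n_exons(tx) - 1L)) {
    if (tx$strand == "+") {
      d_end <- tx$exon_ends[k]; a_start <- tx$exon_starts[k + 1]
      inside <- g_pos > d_end && g_pos < a_start
      if (!inside) next
      d_off <- g_pos - d_end            # distance past the donor boundary
      a_off <- a_start - g_pos          # distance before the acceptor boundary
    } else {
      d_end <- tx$exon_starts[k]; a_start <- tx$exon_ends[k + 1]
      inside <- g_pos < d_end && g_pos > a_start
      if (!inside) next
      d_off <- d_end - g_pos
      a_off <- g_pos - a_start
    }
    if (d_off <= a_off) {
      anchor <- t_to_c(tx, tx$cum_before[k] + tx$exon_lengths[k])
      return(list(pos = anchor$pos, offset = d_off, star = anchor$star))
    } else {
      anchor <- t_to_c(tx, tx$cum_before[k + 1] + 1L)
      return(list(pos = anchor$pos, offset = -a_off, star = anchor$star))
    }
  }
  stop("genomic position not within any intron of the transcript")
}

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive positions with `start <= end`.
#' @return `end - start + 1` (vectorised).
#' @examples
#' interval_length(216495824, 216495941)  # the 118 nt pseudoexon in intron 8
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("interval end before start")
  as.integer(end) - as.integer(start) + 1L
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

extract_genomic <- function(tx, start, end) {
  if (is.null(tx$genome_seq)) stop("transcript model carries no genomic sequence")
  substr(tx$genome_seq, start - tx$genome_start + 1L, end - tx$genome_start + 1L)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in transcript order, reverse-complementing
#' for minus-strand transcripts. Requires the model to carry genomic sequence.
#'
#' @param tx a [transcript_model] with `genome_seq`.
#' @return character string of the mature transcript sequence.
#' @export
spliced_sequence <- function(tx) {
  parts <- mapply(function(s, e) {
    seg <- extract_genomic(tx, s, e)
    if (tx$strand == "-") revcomp(seg) else seg
  }, tx$exon_starts, tx$exon_ends)
  paste0(parts, collapse = "")
}

#' Write / read a transcript model as a 6-column TSV
#'
#' The on-disk form has columns `id`, `chrom`, `strand`, `exon_start`,
#' `exon_end`, `exon_rank` (genomic coordinates, 1-based inclusive, one row
#' per exon in transcript order), preceded by comment lines
#' `#cds_start_c=`/`#cds_end_c=`/`#genome_start=`/`#assembly=`. The genomic
#' sequence, if any, travels separately as FASTA.
#'
#' @param tx a [transcript_model].
#' @param path file path.
#' @return `read_transcript_tsv` returns a [transcript_model] (without
#'   sequence unless `fasta` is given); `write_transcript_tsv` returns the
#'   path invisibly.
#' @export
write_transcript_tsv <- function(tx, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#cds_start_c=", tx$cds_start_c),
    paste0("#cds_end_c=", tx$cds_end_c),
    paste0("#genome_start=", tx$genome_start),
    paste0("#assembly=", tx$assembly),
    paste(c("id", "chrom", "strand", "exon_start", "exon_end", "exon_rank"),
          collapse = "\t")), con)
  for (k in seq_along(tx$exon_starts))
    writeLines(paste(tx$id, tx$chrom, tx$strand, tx$exon_starts[k],
                     tx$exon_ends[k], k, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_transcript_tsv
#' @param fasta optional FASTA path with the plus-strand genomic sequence.
#' @export
read_transcript_tsv <- function(path, fasta = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  val <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  body <- body[order(body$exon_rank), , drop = FALSE]
  genome_seq <- NULL
  genome_start <- as.integer(val("genome_start", "1"))
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    genome_seq <- as.character(ss[[1]])
  }
  transcript_model(
    id = body$id[1], chrom = body$chrom[1], strand = body$strand[1],
    exon_starts = body$exon_start, exon_ends = body$exon_end,
    cds_start_c = as.integer(val("cds_start_c", NA)),
    cds_end_c = as.integer(val("cds_end_c", NA)),
    genome_seq = genome_seq, genome_start = genome_start,
    assembly = val("assembly", "hg19"))
}

#' Read a transcript model from a GFF3 subset
#'
#' Expects `exon` features (one transcript) and optionally `CDS` features; CDS
#' boundaries are converted to transcript coordinates. Parsing is delegated to
#' [rtracklayer::import()].
#'
#' @param path GFF3 file with exon (and CDS) features for one transcript.
#' @param fasta optional FASTA with the plus-strand genomic sequence.
#' @param cds_start_c,cds_end_c CDS boundaries in transcript coordinates, used
#'   when the GFF3 has no CDS features.
#' @return a [transcript_model].
#' @export
read_transcript_gff3 <- function(path, fasta = NULL,
                                 cds_start_c = NULL, cds_end_c = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("no exon features in GFF3")
  strand <- as.character(BiocGenerics::strand(ex))[1]
  ord <- order(BiocGenerics::start(ex), decreasing = (strand == "-"))
  ex <- ex[ord]
  starts <- BiocGenerics::start(ex); ends <- BiocGenerics::end(ex)
  cds <- gr[gr$type == "CDS"]
  tmp <- transcript_model(
    id = as.character(ex$ID %||% ex$Parent %||% "tx")[1],
    chrom = as.character(GenomicRanges::seqnames(ex))[1], strand = strand,
    exon_starts = starts, exon_ends = ends,
    cds_start_c = 1L, cds_end_c = sum(ends - starts + 1) %/% 3 * 3,
    genome_seq = NULL)
  if (length(cds) > 0) {
    g1 <- if (strand == "+") min(BiocGenerics::start(cds)) else max(BiocGenerics::end(cds))
    g2 <- if (strand == "+") max(BiocGenerics::end(cds)) else min(BiocGenerics::start(cds))
    cds_start_c <- g_to_t(tmp, g1)
    cds_end_c <- g_to_t(tmp, g2)
  }
  if (is.null(cds_start_c) || is.null(cds_end_c) || is.na(cds_start_c))
    stop("CDS boundaries neither in GFF3 nor supplied")
  genome_seq <- NULL; genome_start <- 1L
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    genome_seq <- as.character(ss[[1]])
  }
  transcript_model(
    id = tmp$id, chrom = tmp$chrom, strand = strand,
    exon_starts = starts, exon_ends = ends,
    cds_start_c = cds_start_c, cds_end_c = cds_end_c,
    genome_seq = genome_seq, genome_start = genome_start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
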