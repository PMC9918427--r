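# Splice events observed in minigene assays: pseudoexon inclusion, full and
# partial exon skipping, exon extension at either side, and internal exon
# deletion through a novel donor/acceptor pair. Events are expressed against
# a transcript_model; applying one yields the mutant mature transcript.

SPLICE_EVENT_TYPES <- c("pseudoexon_inclusion", "exon_skip",
                        "exon_extension_5", "exon_extension_3",
                        "exon_internal_deletion", "partial_exon_skip")

#' Construct a splice event
#'
#' @param type one of `pseudoexon_inclusion`, `exon_skip`,
#'   `exon_extension_5`, `exon_extension_3`, `exon_internal_deletion`,
#'   `partial_exon_skip`. Extension side 5/3 refers to transcript
#'   orientation: a `_5` extension retains intronic nucleotides adjacent to
#'   the exon's acceptor (upstream) side, `_3` adjacent to its donor side.
#' @param exon exon rank (transcript order) for exon-anchored events.
#' @param pe_start,pe_end genomic interval of the included pseudoexon
#'   (1-based inclusive, `start <= end`), for `pseudoexon_inclusion`.
#' @param extension_nt number of intronic nucleotides retained, for
#'   extensions.
#' @param deleted_nt number of exonic nucleotides lost, for
#'   `partial_exon_skip`.
#' @param side `"5"` or `"3"`: which side of the exon a partial skip removes.
#' @param novel_donor_offset,novel_acceptor_offset for
#'   `exon_internal_deletion`: the novel donor lies `novel_donor_offset` nt
#'   downstream of the canonical acceptor and the novel acceptor
#'   `novel_acceptor_offset` nt upstream of the canonical donor, so those
#'   outer portions of the exon are retained and the centre is lost.
#' @return an object of class `splice_event`.
#' @export
splice_event <- function(type, exon = NULL, pe_start = NULL, pe_end = NULL,
                         extension_nt = NULL, deleted_nt = NULL, side = NULL,
                         novel_donor_offset = NULL,
                         novel_acceptor_offset = NULL) {
  type <- match.arg(type, SPLICE_EVENT_TYPES)
  chk_count <- function(x, nm) {
    if (is.null(x) || length(x) != 1 || is.na(x) || x < 1)
      stop(nm, " must be a count >= 1 for event type ", type)
    as.integer(x)
  }
  ev <- list(type = type)
  if (type == "pseudoexon_inclusion") {
    ev$pe_start <- chk_count(pe_start, "pe_start")
    ev$pe_end <- chk_count(pe_end, "pe_end")
    if (ev$pe_end < ev$pe_start) stop("pseudoexon interval end before start")
  } else {
    ev$exon <- chk_count(exon, "exon")
  }
  if (type %in% c("exon_extension_5", "exon_extension_3"))
    ev$extension_nt <- chk_count(extension_nt, "extension_nt")
  if (type == "partial_exon_skip") {
    ev$deleted_nt <- chk_count(deleted_nt, "deleted_nt")
    ev$side <- match.arg(as.character(side), c("5", "3"))
  }
  if (type == "exon_internal_deletion") {
    ev$novel_donor_offset <- chk_count(novel_donor_offset, "novel_donor_offset")
    ev$novel_acceptor_offset <- chk_count(novel_acceptor_offset,
                                          "novel_acceptor_offset")
  }
  structure(ev, class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  detail <- switch(x$type,
    pseudoexon_inclusion = sprintf("chr?:%d-%d (%d nt)", x$pe_start, x$pe_end,
                                   x$pe_end - x$pe_start + 1L),
    exon_skip = sprintf("exon %d", x$exon),
    exon_extension_5 = ,
    exon_extension_3 = sprintf("exon %d, +%d nt", x$exon, x$extension_nt),
    partial_exon_skip = sprintf("exon %d, -%d nt (%s' side)", x$exon,
                                x$deleted_nt, x$side),
    exon_internal_deletion = sprintf("exon %d, keep %d/%d nt", x$exon,
                                     x$novel_donor_offset,
                                     x$novel_acceptor_offset))
  cat("splice_event:", x$type, detail, "\n")
  invisible(x)
}

#' Net transcript-length change of an event
#'
#' @param tx a [transcript_model].
#' @param ev a [splice_event()].
#' @return signed integer: insertion sizes positive, deletions negative.
#' @export
event_size <- function(tx, ev) {
  switch(ev$type,
    pseudoexon_inclusion = ev$pe_end - ev$pe_start + 1L,
    exon_skip = -tx$exon_lengths[ev$exon],
    exon_extension_5 = ev$extension_nt,
    exon_extension_3 = ev$extension_nt,
    partial_exon_skip = -ev$deleted_nt,
    exon_internal_deletion = -(tx$exon_lengths[ev$exon] -
                               ev$novel_donor_offset - ev$novel_acceptor_offset))
}

#' In-frame or frameshift from an event size
#'
#' @param event_size_nt absolute event size in nucleotides (>= 1).
#' @return `"in_frame"` when the size is a multiple of 3, else
#'   `"frameshift"`.
#' @examples
#' frame_effect(87)   # in_frame
#' frame_effect(130)  # frameshift
#' @export
frame_effect <- function(event_size_nt) {
  event_size_nt <- abs(as.integer(event_size_nt))
  if (any(event_size_nt < 1)) stop("event size must be >= 1")
  ifelse(event_size_nt %% 3L == 0L, "in_frame", "frameshift")
}

# Locate the intron (by upstream-exon rank, transcript order) that fully
# contains a genomic interval; error when it straddles a boundary or lies in
# an exon.
containing_intron <- function(tx, g_start, g_end) {
  for (k in seq_len(n_exons(tx) - 1L)) {
    if (tx$strand == "+") {
      lo <- tx$exon_ends[k] + 1L; hi <- tx$exon_starts[k + 1L] - 1L
    } else {
      lo <- tx$exon_ends[k + 1L] + 1L; hi <- tx$exon_starts[k] - 1L
    }
    if (g_start >= lo && g_end <= hi) return(k)
  }
  stop("pseudoexon interval chr:", g_start, "-", g_end,
       " is not contained in any intron of ", tx$id)
}

# Mutant exon structure: data frame of genomic segments (start, end) in
# transcript order, with a `novel` flag for nucleotides absent from the
# mature wild-type transcript (pseudoexon or retained-intron sequence).
mutant_segments <- function(tx, ev) {
  seg <- data.frame(start = tx$exon_starts, end = tx$exon_ends,
                    novel = FALSE)
  minus <- tx$strand == "-"
  if (ev$type != "pseudoexon_inclusion") {
    k <- ev$exon
    if (k < 1 || k > n_exons(tx)) stop("exon index out of range")
  }
  switch(ev$type,
    pseudoexon_inclusion = {
      k <- containing_intron(tx, ev$pe_start, ev$pe_end)
      pe <- data.frame(start = ev$pe_start, end = ev$pe_end, novel = TRUE)
      seg <- rbind(seg[seq_len(k), ], pe,
                   seg[seq(k + 1L, nrow(seg)), ])
    },
    exon_skip = {
      seg <- seg[-k, , drop = FALSE]
    },
    exon_extension_5 = {
      n <- ev$extension_nt
      intron_len <- if (k == 1L) 0L else abs(
        if (minus) tx$exon_starts[k - 1L] - tx$exon_ends[k]
        else tx$exon_starts[k] - tx$exon_ends[k - 1L]) - 1L
      if (k == 1L || n >= intron_len)
        stop("extension exceeds the upstream intron")
      if (minus) seg$end[k] <- seg$end[k] + n else seg$start[k] <- seg$start[k] - n
      seg$novel[k] <- NA  # partially novel; refined below
    },
    exon_extension_3 = {
      n <- ev$extension_nt
      intron_len <- if (k == n_exons(tx)) 0L else abs(
        if (minus) tx$exon_starts[k] - tx$exon_ends[k + 1L]
        else tx$exon_starts[k + 1L] - tx$exon_ends[k]) - 1L
      if (k == n_exons(tx) || n >= intron_len)
        stop("extension exceeds the downstream intron")
      if (minus) seg$start[k] <- seg$start[k] - n else seg$end[k] <- seg$end[k] + n
      seg$novel[k] <- NA
    },
    partial_exon_skip = {
      n <- ev$deleted_nt
      if (n >= tx$exon_lengths[k]) stop("partial skip removes the whole exon")
      del5 <- identical(ev$side, "5")
      if ((del5 && !minus) || (!del5 && minus)) seg$start[k] <- seg$start[k] + n
      else seg$end[k] <- seg$end[k] - n
    },
    exon_internal_deletion = {
      keep5 <- ev$novel_donor_offset; keep3 <- ev$novel_acceptor_offset
      len <- tx$exon_lengths[k]
      if (keep5 + keep3 >= len)
        stop("novel splice-site offsets leave nothing to delete")
      if (minus) {
        a <- data.frame(start = tx$exon_ends[k] - keep5 + 1L,
                        end = tx$exon_ends[k], novel = FALSE)
        b <- data.frame(start = tx$exon_starts[k],
                        end = tx$exon_starts[k] + keep3 - 1L, novel = FALSE)
      } else {
        a <- data.frame(start = tx$exon_starts[k],
                        end = tx$exon_starts[k] + keep5 - 1L, novel = FALSE)
        b <- data.frame(start = tx$exon_ends[k] - keep3 + 1L,
                        end = tx$exon_ends[k], novel = FALSE)
      }
      seg <- rbind(if (k > 1) seg[seq_len(k - 1L), ], a, b,
                   if (k < nrow(seg)) seg[seq(k + 1L, nrow(seg)), ])
    })
  rownames(seg) <- NULL
  seg
}

#' Apply a splice event to a transcript
#'
#' Builds the mutant mature transcript: a pseudoexon inclusion splices the
#' (strand-corrected) pseudoexon sequence between the flanking exons of the
#' intron containing it; an exon skip removes the full exon; extensions
#' retain the stated intronic nucleotides adjacent to the canonical site;
#' partial skips and internal deletions remove the stated exonic span. The
#' output length equals the input length plus [event_size()].
#'
#' @param tx a [transcript_model] carrying genomic sequence.
#' @param ev a [splice_event()].
#' @return an object of class `mutant_transcript`: list with `seq` (mutant
#'   spliced sequence), `segments` (genomic segments in transcript order),
#'   `novel_range` (mutant-transcript coordinates of nucleotides absent from
#'   the wild type, or NULL), `junctions` (cumulative mutant exon-exon
#'   junction positions) and `cds_start` (mutant-transcript position of the
#'   original translation start).
#' @export
apply_event <- function(tx, ev) {
  stopifnot(inherits(tx, "transcript_model"), inherits(ev, "splice_event"))
  seg <- mutant_segments(tx, ev)
  seqs <- mapply(function(s, e) {
    x <- extract_genomic(tx, s, e)
    if (tx$strand == "-") revcomp(x) else x
  }, seg$start, seg$end)
  lens <- seg$end - seg$start + 1L
  cum <- cumsum(lens)
  mseq <- paste0(seqs, collapse = "")

  # mutant-transcript range of novel nucleotides
  novel_range <- NULL
  if (ev$type == "pseudoexon_inclusion") {
    i <- which(seg$novel)
    novel_range <- c(cum[i] - lens[i] + 1L, cum[i])
  } else if (ev$type %in% c("exon_extension_5", "exon_extension_3")) {
    i <- which(is.na(seg$novel))
    if (ev$type == "exon_extension_5")
      novel_range <- c(cum[i] - lens[i] + 1L,
                       cum[i] - lens[i] + ev$extension_nt)
    else
      novel_range <- c(cum[i] - ev$extension_nt + 1L, cum[i])
  }

  # mutant position of the original translation start
  g0 <- t_to_g(tx, tx$cds_start_c)
  cds_start <- NA_integer_
  for (i in seq_len(nrow(seg))) {
    s <- seg$start[i]; e <- seg$end[i]
    if (!isTRUE(seg$novel[i]) || is.na(seg$novel[i])) {
      if (g0 >= s && g0 <= e) {
        off <- if (tx$strand == "+") g0 - s else e - g0
        cds_start <- cum[i] - lens[i] + off + 1L
        break
      }
    }
  }
  if (is.na(cds_start))
    stop("event removes the translation start codon position")

  structure(list(seq = mseq, segments = seg, novel_range = novel_range,
                 junctions = cum[-length(cum)], cds_start = cds_start,
                 event = ev),
            class = "mutant_transcript")
}
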