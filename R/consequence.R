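# Protein-level consequences of splice events: translate the mutant CDS from
# the canonical start, compare against the wild-type protein, and emit the
# HGVS p. description (three-letter codes, "*" for stop, "fs*N" for
# frameshifts, "ins*N" when the first stop arises within inserted codons
# before any native residue is altered).

EFFECT_CLASSES <- c("ptc_frameshift", "ptc_in_inserted", "inframe_deletion",
                    "inframe_insertion", "no_change")

aa3 <- function(aa1) {
  code <- Biostrings::AMINO_ACID_CODE
  out <- vapply(strsplit(paste0(aa1, collapse = ""), "")[[1]], function(a)
    if (a == "*") "*" else unname(code[a]), "")
  paste0(out, collapse = "")
}

# translate a nucleotide string codon-by-codon to the first stop (engine
# route uses the Biostrings genetic code); returns residues (1-letter, stop
# excluded), whether a stop terminated scanning, and the 1-based nt index of
# the stop codon's first base within `seq`.
translate_to_stop <- function(seq) {
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L)
    return(list(residues = "", terminated = FALSE, stop_nt = NA_integer_))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n_codon * 3L)),
    genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0)
    list(residues = substr(aa, 1L, stop_at - 1L), terminated = TRUE,
         stop_nt = (as.integer(stop_at) - 1L) * 3L + 1L)
  else
    list(residues = aa, terminated = FALSE, stop_nt = NA_integer_)
}

new_protein_consequence <- function(hgvs_p, effect_class, nmd = FALSE) {
  structure(list(hgvs_p = hgvs_p, effect_class = effect_class,
                 nmd_predicted = nmd), class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("p.%s [%s]%s\n", x$hgvs_p, x$effect_class,
              if (x$nmd_predicted) " NMD-predicted" else ""))
  invisible(x)
}

common_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0L) n else d[1] - 1L
}

common_suffix_len <- function(a, b, max_len) {
  s <- 0L
  while (s < max_len && a[length(a) - s] == b[length(b) - s]) s <- s + 1L
  s
}

#' Predict the protein consequence of a single splice event
#'
#' Translates the mutant CDS from the canonical start codon and derives the
#' HGVS p. description by comparison with the wild-type protein:
#'
#' * a stop arising within inserted (pseudoexon or retained-intron)
#'   nucleotides gives `Xaa#_Yaa#ins*N`, with N counting the novel residues
#'   from the insertion point, stop included -- this covers both in-frame and
#'   frameshifting inclusions whose stop precedes any shifted native codon;
#' * an in-frame event whose translation reaches the normal terminal stop
#'   gives `Xaa#_Yaa#del` (placed 3'-most), `ins`, or `delins`;
#' * otherwise a premature stop downstream gives `Xaa#Yaafs*N` (N counts from
#'   the first changed residue, stop included) or, when the first changed
#'   codon is itself the stop, the nonsense form `Xaa#*`;
#' * an unchanged protein gives `=`.
#'
#' NMD is flagged when a premature stop ends 50 nt or more upstream of the
#' last exon-exon junction of the mutant transcript (informational only,
#' never used for classification).
#'
#' @param tx a [transcript_model] with sequence and CDS.
#' @param ev a [splice_event()].
#' @return a `protein_consequence` (fields `hgvs_p`, `effect_class`,
#'   `nmd_predicted`).
#' @export
predict_protein_consequence <- function(tx, ev) {
  wt_cds <- substr(spliced_sequence(tx), tx$cds_start_c, tx$cds_end_c)
  wt <- translate_to_stop(wt_cds)
  if (!wt$terminated) stop("wild-type CDS lacks a terminal stop codon")
  W <- strsplit(wt$residues, "")[[1]]

  mut <- apply_event(tx, ev)
  mt <- translate_to_stop(substr(mut$seq, mut$cds_start, nchar(mut$seq)))
  M <- strsplit(mt$residues, "")[[1]]

  if (mt$terminated && length(M) == length(W) && all(M == W))
    return(new_protein_consequence("=", "no_change", FALSE))

  stop_nt_abs <- if (mt$terminated) mut$cds_start + mt$stop_nt - 1L
                 else NA_integer_
  nmd_flag <- FALSE
  if (mt$terminated && length(mut$junctions) > 0)
    nmd_flag <- (max(mut$junctions) - (stop_nt_abs + 2L)) >= 50L

  p <- common_prefix_len(W, M)

  if (!mt$terminated) {
    warning("no stop codon before the end of the mutant transcript; ",
            "reporting an open-ended frameshift")
    first <- p + 1L
    hg <- sprintf("%s%d%sfs*?", aa3(W[first]), first,
                  if (first <= length(M)) aa3(M[first]) else "?")
    return(new_protein_consequence(hg, "ptc_frameshift", FALSE))
  }

  # stop codon entirely within inserted nucleotides -> ins*N
  if (!is.null(mut$novel_range) &&
      stop_nt_abs >= mut$novel_range[1] &&
      stop_nt_abs + 2L <= mut$novel_range[2]) {
    N <- length(M) - p + 1L
    nxt <- if (p + 1L <= length(W)) aa3(W[p + 1L]) else "Ter"
    return(new_protein_consequence(
      sprintf("%s%d_%s%dins*%d", aa3(W[p]), p, nxt, p + 1L, N),
      "ptc_in_inserted", nmd_flag))
  }

  size <- event_size(tx, ev)
  in_frame_clean <- size %% 3L == 0L &&
    length(M) == length(W) + size %/% 3L
  if (in_frame_clean) {
    s <- common_suffix_len(W, M, min(length(W), length(M)) - p)
    if (length(M) < length(W) && p + s >= length(M)) {
      d <- length(W) - length(M)
      i <- p + 1L; j <- p + d
      hg <- if (d == 1L) sprintf("%s%ddel", aa3(W[i]), i)
            else sprintf("%s%d_%s%ddel", aa3(W[i]), i, aa3(W[j]), j)
      return(new_protein_consequence(hg, "inframe_deletion", FALSE))
    }
    if (length(M) > length(W) && p + s >= length(W)) {
      ins <- M[seq(p + 1L, length(M) - (length(W) - p))]
      nxt <- if (p + 1L <= length(W)) aa3(W[p + 1L]) else "Ter"
      return(new_protein_consequence(
        sprintf("%s%d_%s%dins%s", aa3(W[p]), p, nxt, p + 1L, aa3(ins)),
        "inframe_insertion", FALSE))
    }
    i <- p + 1L; j <- length(W) - s
    repl <- M[seq(p + 1L, length(M) - s)]
    hg <- sprintf("%s%d_%s%ddelins%s", aa3(W[i]), i, aa3(W[j]), j, aa3(repl))
    cls <- if (length(M) <= length(W)) "inframe_deletion"
           else "inframe_insertion"
    return(new_protein_consequence(hg, cls, FALSE))
  }

  # premature termination
  first <- p + 1L
  if (length(M) == p) {
    anchor <- if (first <= length(W)) sprintf("%s%d", aa3(W[first]), first)
              else sprintf("Ter%d", first)
    return(new_protein_consequence(paste0(anchor, "*"),
                                   "ptc_frameshift", nmd_flag))
  }
  N <- length(M) - p + 1L
  new_protein_consequence(
    sprintf("%s%d%sfs*%d", aa3(W[first]), first, aa3(M[first]), N),
    "ptc_frameshift", nmd_flag)
}

#' Splice assay outcome for one variant
#'
#' Encodes what a minigene assay showed: the set of splice events and whether
#' conventionally spliced transcript remained. A "full effect" means no
#' conventional transcript was detected.
#'
#' @param variant HGVS c. description (character) or `hgvs_variant`.
#' @param events list of [splice_event()] objects (possibly empty for a
#'   variant without splice effect).
#' @param conventional_transcript_present logical; must be TRUE when `events`
#'   is empty.
#' @param observed logical; observed (assayed) effects are serialised without
#'   enclosing parentheses, predicted-only ones with.
#' @return an object of class `splice_outcome`.
#' @export
splice_outcome <- function(variant, events = list(),
                           conventional_transcript_present = FALSE,
                           observed = TRUE) {
  if (length(events) == 0 && !conventional_transcript_present)
    stop("an outcome needs at least one event or conventional transcript")
  stopifnot(all(vapply(events, inherits, TRUE, "splice_event")))
  structure(list(variant = variant, events = events,
                 conventional_transcript_present = conventional_transcript_present,
                 observed = observed),
            class = "splice_outcome")
}

#' Is the splice effect full (no conventional transcript left)?
#' @param outcome a [splice_outcome()].
#' @return logical.
#' @export
is_full_effect <- function(outcome)
  length(outcome$events) > 0 && !outcome$conventional_transcript_present

#' Protein consequences for a complete assay outcome
#'
#' One consequence per event, with `=` appended when conventionally spliced
#' transcript remains. Use [format_consequences()] for the serialised
#' `p.[...]` form.
#'
#' @param tx a [transcript_model] with sequence.
#' @param outcome a [splice_outcome()].
#' @return list of `protein_consequence` objects.
#' @export
consequence_for_outcome <- function(tx, outcome) {
  out <- lapply(outcome$events, function(ev)
    predict_protein_consequence(tx, ev))
  if (outcome$conventional_transcript_present)
    out <- c(out, list(new_protein_consequence("=", "no_change", FALSE)))
  out
}

#' Serialise protein consequences as an HGVS p. string
#'
#' Multiple alternative consequences are joined with commas inside brackets
#' (`p.[...]`); experimentally observed effects are written without enclosing
#' parentheses, predicted-only effects with them.
#'
#' @param consequences list of `protein_consequence` objects (or one).
#' @param observed logical; controls the parentheses convention.
#' @return character, e.g. `"p.[Arg3037_Val3087del,Val3049*]"`.
#' @export
format_consequences <- function(consequences, observed = TRUE) {
  if (inherits(consequences, "protein_consequence"))
    consequences <- list(consequences)
  parts <- vapply(consequences, function(x) x$hgvs_p, "")
  body <- if (length(parts) > 1)
    paste0("[", paste(parts, collapse = ","), "]")
  else parts
  if (observed) paste0("p.", body) else paste0("p.(", body, ")")
}
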