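# Brute-force reference implementation of the consequence prediction, used
# to validate the engine. Deliberately independent of the engine's machinery:
# it builds a per-base genomic lookup table by walking the exons, performs
# the splice surgery as raw character-vector slicing on that table, uses its
# own complement map and codon table, and derives the HGVS string by direct
# wild-type/mutant comparison with naive loops.

BF_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

BF_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

BF_AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
            E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
            M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
            Y = "Tyr", V = "Val", "*" = "*")

bf_aa3 <- function(a) paste(unname(BF_AA3[a]), collapse = "")

bf_translate <- function(chars) {
  n <- length(chars) %/% 3L
  if (n == 0L) return(list(aa = character(0), stop_idx = NA_integer_))
  codons <- vapply(seq_len(n), function(i)
    paste0(chars[(3L * i - 2L):(3L * i)], collapse = ""), "")
  aa <- unname(BF_CODONS[codons])
  stop_i <- which(aa == "*")
  if (length(stop_i) > 0)
    list(aa = aa[seq_len(stop_i[1] - 1L)], stop_idx = stop_i[1])
  else
    list(aa = aa, stop_idx = NA_integer_)
}

# genomic coordinate of every transcript base, walking exons in rank order
bf_base_table <- function(tx) {
  out <- integer(0)
  for (k in seq_along(tx$exon_starts)) {
    g <- tx$exon_starts[k]:tx$exon_ends[k]
    if (tx$strand == "-") g <- rev(g)
    out <- c(out, g)
  }
  out
}

bf_seq_at <- function(tx, g_positions)
  vapply(g_positions, function(g) {
    ch <- substr(tx$genome_seq, g - tx$genome_start + 1L,
                 g - tx$genome_start + 1L)
    if (tx$strand == "-") unname(BF_COMPLEMENT[ch]) else ch
  }, "")

#' Brute-force splice-consequence oracle
#'
#' Reference route used to cross-check [predict_protein_consequence()]:
#' performs the event as direct slice-and-concatenate surgery on a per-base
#' lookup table of the spliced transcript, translates with its own codon
#' table, and emits the HGVS p. description by direct wild-type/mutant
#' comparison with naive loops. Kept free of the engine's coordinate and
#' sequence machinery.
#'
#' @param tx a [transcript_model] with sequence.
#' @param ev a [splice_event()].
#' @return list with `hgvs_p`, `effect_class`, `nmd_predicted` (same
#'   contract as `protein_consequence`, as a plain list).
#' @export
bf_splice_consequence <- function(tx, ev) {
  gtab <- bf_base_table(tx)
  wt_chars <- bf_seq_at(tx, gtab)
  L <- length(wt_chars)
  minus <- tx$strand == "-"
  exon_of <- rep(seq_along(tx$exon_starts), times = tx$exon_lengths)
  cuts <- cumsum(tx$exon_lengths)

  # --- surgery: orig_map gives, per mutant base, its WT transcript index
  #     (NA for inserted bases); ins_chars the inserted characters
  if (ev$type == "pseudoexon_inclusion") {
    cut <- NA_integer_
    for (k in seq_len(length(cuts) - 1L)) {
      g1 <- gtab[cuts[k]]; g2 <- gtab[cuts[k] + 1L]
      inside <- if (minus) ev$pe_end < g1 && ev$pe_start > g2
                else ev$pe_start > g1 && ev$pe_end < g2
      if (inside) { cut <- cuts[k]; break }
    }
    if (is.na(cut)) stop("oracle: pseudoexon not inside any intron")
    g <- ev$pe_start:ev$pe_end
    if (minus) g <- rev(g)
    ins_chars <- bf_seq_at(tx, g)
    orig_map <- c(seq_len(cut), rep(NA_integer_, length(ins_chars)),
                  seq(cut + 1L, L))
    mut_chars <- c(wt_chars[seq_len(cut)], ins_chars,
                   wt_chars[seq(cut + 1L, L)])
    mut_exon_sizes <- append(tx$exon_lengths, length(ins_chars), after = k)
  } else if (ev$type == "exon_skip") {
    keep <- which(exon_of != ev$exon)
    orig_map <- keep
    mut_chars <- wt_chars[keep]
    mut_exon_sizes <- tx$exon_lengths[-ev$exon]
  } else if (ev$type %in% c("exon_extension_5", "exon_extension_3")) {
    k <- ev$exon; n <- ev$extension_nt
    idx <- which(exon_of == k)
    if (ev$type == "exon_extension_5") {
      first_g <- gtab[idx[1]]
      ext_g <- if (minus) seq(first_g + n, first_g + 1L)
               else seq(first_g - n, first_g - 1L)
      ins_at <- idx[1] - 1L
    } else {
      last_g <- gtab[idx[length(idx)]]
      ext_g <- if (minus) seq(last_g - 1L, last_g - n)
               else seq(last_g + 1L, last_g + n)
      ins_at <- idx[length(idx)]
    }
    ins_chars <- bf_seq_at(tx, ext_g)
    orig_map <- append(seq_len(L), rep(NA_integer_, n), after = ins_at)
    mut_chars <- append(wt_chars, ins_chars, after = ins_at)
    mut_exon_sizes <- tx$exon_lengths
    mut_exon_sizes[k] <- mut_exon_sizes[k] + n
  } else if (ev$type == "partial_exon_skip") {
    k <- ev$exon; n <- ev$deleted_nt
    idx <- which(exon_of == k)
    drop <- if (ev$side == "5") idx[seq_len(n)]
            else idx[seq(length(idx) - n + 1L, length(idx))]
    orig_map <- seq_len(L)[-drop]
    mut_chars <- wt_chars[-drop]
    mut_exon_sizes <- tx$exon_lengths
    mut_exon_sizes[k] <- mut_exon_sizes[k] - n
  } else if (ev$type == "exon_internal_deletion") {
    k <- ev$exon
    idx <- which(exon_of == k)
    keep_idx <- c(idx[seq_len(ev$novel_donor_offset)],
                  idx[seq(length(idx) - ev$novel_acceptor_offset + 1L,
                          length(idx))])
    drop <- setdiff(idx, keep_idx)
    orig_map <- seq_len(L)[-drop]
    mut_chars <- wt_chars[-drop]
    # a novel donor/acceptor pair splices the centre out: two smaller exons
    mut_exon_sizes <- append(tx$exon_lengths, ev$novel_acceptor_offset,
                             after = k)
    mut_exon_sizes[k] <- ev$novel_donor_offset
  } else stop("unknown event type ", ev$type)

  novel <- is.na(orig_map)
  start_mut <- which(!novel & orig_map == tx$cds_start_c)
  if (length(start_mut) == 0)
    stop("oracle: event removes the translation start position")
  start_mut <- start_mut[1]

  wt_tr <- bf_translate(wt_chars[seq(tx$cds_start_c, L)])
  mut_tr <- bf_translate(mut_chars[seq(start_mut, length(mut_chars))])
  W <- wt_tr$aa; M <- mut_tr$aa

  if (!is.na(mut_tr$stop_idx) && length(M) == length(W) &&
      (length(W) == 0 || all(M == W)))
    return(list(hgvs_p = "=", effect_class = "no_change",
                nmd_predicted = FALSE))

  p <- 0L
  while (p < min(length(W), length(M)) && W[p + 1L] == M[p + 1L]) p <- p + 1L

  if (is.na(mut_tr$stop_idx)) {
    warning("oracle: no stop codon before transcript end")
    first <- p + 1L
    return(list(hgvs_p = sprintf("%s%d%sfs*?", bf_aa3(W[first]), first,
                                 if (first <= length(M)) bf_aa3(M[first]) else "?"),
                effect_class = "ptc_frameshift", nmd_predicted = FALSE))
  }

  stop_first_nt <- start_mut + (mut_tr$stop_idx - 1L) * 3L
  junctions <- cumsum(mut_exon_sizes)
  junctions <- junctions[-length(junctions)]
  nmd <- length(junctions) > 0 &&
    (max(junctions) - (stop_first_nt + 2L)) >= 50L

  if (any(novel) && all(novel[stop_first_nt:(stop_first_nt + 2L)])) {
    N <- length(M) - p + 1L
    nxt <- if (p + 1L <= length(W)) bf_aa3(W[p + 1L]) else "Ter"
    return(list(hgvs_p = sprintf("%s%d_%s%dins*%d", bf_aa3(W[p]), p,
                                 nxt, p + 1L, N),
                effect_class = "ptc_in_inserted", nmd_predicted = nmd))
  }

  size <- length(mut_chars) - L
  if (size %% 3L == 0L && length(M) == length(W) + size %/% 3L) {
    s <- 0L
    while (s < min(length(W), length(M)) - p &&
           W[length(W) - s] == M[length(M) - s]) s <- s + 1L
    if (length(M) < length(W) && p + s >= length(M)) {
      d <- length(W) - length(M)
      i <- p + 1L; j <- p + d
      hg <- if (d == 1L) sprintf("%s%ddel", bf_aa3(W[i]), i)
            else sprintf("%s%d_%s%ddel", bf_aa3(W[i]), i, bf_aa3(W[j]), j)
      return(list(hgvs_p = hg, effect_class = "inframe_deletion",
                  nmd_predicted = FALSE))
    }
    if (length(M) > length(W) && p + s >= length(W)) {
      ins <- M[seq(p + 1L, length(M) - (length(W) - p))]
      nxt <- if (p + 1L <= length(W)) bf_aa3(W[p + 1L]) else "Ter"
      return(list(hgvs_p = sprintf("%s%d_%s%dins%s", bf_aa3(W[p]), p,
                                   nxt, p + 1L, bf_aa3(ins)),
                  effect_class = "inframe_insertion", nmd_predicted = FALSE))
    }
    i <- p + 1L; j <- length(W) - s
    repl <- M[seq(p + 1L, length(M) - s)]
    return(list(hgvs_p = sprintf("%s%d_%s%ddelins%s", bf_aa3(W[i]), i,
                                 bf_aa3(W[j]), j, bf_aa3(repl)),
                effect_class = if (length(M) <= length(W)) "inframe_deletion"
                               else "inframe_insertion",
                nmd_predicted = FALSE))
  }

  first <- p + 1L
  if (length(M) == p)
    return(list(hgvs_p = sprintf("%s%d*", bf_aa3(W[first]), first),
                effect_class = "ptc_frameshift", nmd_predicted = nmd))
  list(hgvs_p = sprintf("%s%d%sfs*%d", bf_aa3(W[first]), first,
                        bf_aa3(M[first]), length(M) - p + 1L),
       effect_class = "ptc_frameshift", nmd_predicted = nmd)
}
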