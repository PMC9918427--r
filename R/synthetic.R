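# Seeded generators for every input the pipeline needs: multi-exon
# transcripts (either strand) with a valid CDS and full intronic sequence,
# planted splice events with oracle-derived ground truth, annotated variant
# tables with VCF output, and proband cohorts with known expected statuses.

STOP_CODONS <- c("TAA", "TAG", "TGA")
# a short cassette carrying a stop codon in all three reading frames, placed
# at the start of the 3' UTR so frameshifted reads always terminate
UTR3_STOP_CASSETTE <- "TTAATTAATTAA"

#' Simulation configuration
#'
#' Reproducible settings for the synthetic generators: identical seeds give
#' identical outputs. Defaults emulate a compact disease-gene locus: six
#' exons of 60-240 nt separated by 250-2,000 nt introns, ~45% GC, a
#' 100-proband cohort with a genotype mixture echoing a largely mono-allelic
#' referral cohort (37% two (likely) pathogenic alleles, 12% one plus a
#' causative VUS, 5% two VUS, 5% with a benign-class pair, 31% mono-allelic,
#' 10% without candidate alleles).
#'
#' @param seed integer seed; set NA to leave the RNG state untouched (for
#'   drawing several objects inside one seeded block).
#' @param n_exons number of exons (>= 3).
#' @param exon_length,intron_length,utr5_length,utr3_length length ranges
#'   (nt).
#' @param gc_content GC fraction of generated sequence.
#' @param n_variants variants per generated annotation table.
#' @param n_probands cohort size.
#' @param mixture_weights named weights over genotype categories
#'   `plp_pair`, `plp_vus`, `vus_vus`, `benign_pair`, `mono`, `none`;
#'   must sum to 1.
#' @param genome_start genomic coordinate assigned to the first simulated
#'   base.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_exons = 6L, exon_length = c(60L, 240L),
                       intron_length = c(250L, 2000L),
                       utr5_length = c(30L, 90L), utr3_length = c(60L, 120L),
                       gc_content = 0.45, n_variants = 50L,
                       n_probands = 100L,
                       mixture_weights = c(plp_pair = 0.37, plp_vus = 0.12,
                                           vus_vus = 0.05, benign_pair = 0.05,
                                           mono = 0.31, none = 0.10),
                       genome_start = 10001L) {
  if (n_exons < 3L) stop("need at least three exons")
  if (exon_length[1] < 30L) stop("exons shorter than 30 nt are not supported")
  if (abs(sum(mixture_weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  req <- c("plp_pair", "plp_vus", "vus_vus", "benign_pair", "mono", "none")
  if (!setequal(names(mixture_weights), req))
    stop("mixture weights must be named ", paste(req, collapse = ", "))
  structure(list(seed = seed, n_exons = as.integer(n_exons),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 utr5_length = as.integer(utr5_length),
                 utr3_length = as.integer(utr3_length),
                 gc_content = gc_content, n_variants = as.integer(n_variants),
                 n_probands = as.integer(n_probands),
                 mixture_weights = mixture_weights[req],
                 genome_start = as.integer(genome_start)),
            class = "sim_config")
}

maybe_seed <- function(cfg) {
  if (!is.na(cfg$seed)) set.seed(cfg$seed)
}

random_dna <- function(n, gc = 0.45) {
  if (n == 0L) return("")
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

random_cds <- function(n_codons, gc = 0.45) {
  # internal codons drawn from the 61 sense codons, uniform
  sense <- setdiff(names(BF_CODONS), STOP_CODONS)
  body <- if (n_codons > 2L)
    paste0(sample(sense, n_codons - 2L, replace = TRUE), collapse = "")
  else ""
  paste0("ATG", body, sample(STOP_CODONS, 1L))
}

#' Generate a random multi-exon transcript with genomic sequence
#'
#' Produces a transcript on a random strand whose spliced sequence carries a
#' 5' UTR, a CDS (ATG start, in-frame terminal stop, no internal stop,
#' length divisible by 3) distributed across the exons, and a 3' UTR that
#' begins with a stop cassette covering all three frames, so that
#' frameshifted reads terminate. Introns are random sequence available for
#' pseudoexon construction.
#'
#' @param cfg a [sim_config()]; its seed is applied unless NA.
#' @param id transcript identifier.
#' @param strand `"+"`, `"-"`, or `"random"` (default).
#' @return a [transcript_model] with genomic sequence.
#' @export
make_transcript <- function(cfg = sim_config(), id = "SYNTX1",
                            strand = "random") {
  maybe_seed(cfg)
  rint <- function(rng) if (rng[1] == rng[2]) rng[1]
                        else sample(seq(rng[1], rng[2]), 1L)
  strand <- if (identical(strand, "random")) sample(c("+", "-"), 1L)
            else match.arg(strand, c("+", "-"))
  exon_len <- vapply(seq_len(cfg$n_exons), function(i)
    rint(cfg$exon_length), 1L)
  total <- sum(exon_len)
  utr5 <- rint(cfg$utr5_length)
  utr3 <- rint(cfg$utr3_length)
  cds_len <- total - utr5 - utr3
  utr3 <- utr3 + cds_len %% 3L
  cds_len <- cds_len - cds_len %% 3L
  if (cds_len < 60L)
    stop("infeasible length constraints: CDS would be shorter than 60 nt")
  spliced <- paste0(random_dna(utr5, cfg$gc_content),
                    random_cds(cds_len %/% 3L),
                    UTR3_STOP_CASSETTE,
                    random_dna(utr3 - nchar(UTR3_STOP_CASSETTE),
                               cfg$gc_content))
  # plus-strand layout: flank / exon1 / intron1 / ... / exonN / flank
  intron_len <- vapply(seq_len(cfg$n_exons - 1L), function(i)
    rint(cfg$intron_length), 1L)
  flank <- 200L
  pieces <- character(0)
  starts <- integer(cfg$n_exons); ends <- integer(cfg$n_exons)
  pos <- flank
  offset_in_spliced <- 0L
  pieces <- random_dna(flank, cfg$gc_content)
  for (k in seq_len(cfg$n_exons)) {
    starts[k] <- pos + 1L
    ends[k] <- pos + exon_len[k]
    pieces <- paste0(pieces, substr(spliced, offset_in_spliced + 1L,
                                    offset_in_spliced + exon_len[k]))
    offset_in_spliced <- offset_in_spliced + exon_len[k]
    pos <- pos + exon_len[k]
    if (k < cfg$n_exons) {
      pieces <- paste0(pieces, random_dna(intron_len[k], cfg$gc_content))
      pos <- pos + intron_len[k]
    }
  }
  pieces <- paste0(pieces, random_dna(flank, cfg$gc_content))
  glen <- nchar(pieces)
  if (strand == "-") {
    pieces <- revcomp(pieces)
    new_starts <- glen - ends + 1L
    new_ends <- glen - starts + 1L
    starts <- new_starts; ends <- new_ends  # still in transcript order
  }
  transcript_model(id = id, chrom = "chrS", strand = strand,
                   exon_starts = starts + cfg$genome_start - 1L,
                   exon_ends = ends + cfg$genome_start - 1L,
                   cds_start_c = utr5 + 1L, cds_end_c = utr5 + cds_len,
                   genome_seq = pieces, genome_start = cfg$genome_start,
                   assembly = "synthetic")
}

# exon ranks whose coding part can host an event without touching the start
# or terminal stop codon
eligible_exons <- function(tx) {
  ok <- logical(0)
  for (k in seq_len(n_exons(tx))) {
    a <- tx$cum_before[k] + 1L
    b <- tx$cum_before[k] + tx$exon_lengths[k]
    ok <- c(ok, a > tx$cds_start_c + 2L && b < tx$cds_end_c - 2L)
  }
  which(ok)
}

#' Plant a random splice event with oracle-derived ground truth
#'
#' Samples one of the six event classes (pseudoexon inclusion, exon skip,
#' 5'/3' exon extension, partial skip, internal deletion) at a random
#' CDS-internal location of the transcript and computes the expected protein
#' consequence with the brute-force oracle [bf_splice_consequence()], for
#' parameter-recovery tests of the engine.
#'
#' @param tx a [transcript_model] from [make_transcript()].
#' @param cfg a [sim_config()]; its seed is applied unless NA.
#' @param types event classes to sample from (default all six).
#' @return list with `event` (a [splice_event()]) and `truth` (the oracle's
#'   consequence list).
#' @export
plant_splice_event <- function(tx, cfg = sim_config(seed = NA),
                               types = SPLICE_EVENT_TYPES) {
  maybe_seed(cfg)
  elig <- eligible_exons(tx)
  if (length(elig) == 0) stop("transcript has no CDS-internal exon")
  type <- sample(types, 1L)
  minus <- tx$strand == "-"
  ev <- switch(type,
    pseudoexon_inclusion = {
      # an intron whose flanking junction lies inside the CDS
      ks <- Filter(function(k) {
        j <- tx$cum_before[k] + tx$exon_lengths[k]
        j >= tx$cds_start_c + 3L && j <= tx$cds_end_c - 3L
      }, seq_len(n_exons(tx) - 1L))
      k <- if (length(ks) == 1L) ks else sample(ks, 1L)
      ilo <- if (minus) tx$exon_ends[k + 1L] + 1L else tx$exon_ends[k] + 1L
      ihi <- if (minus) tx$exon_starts[k] - 1L else tx$exon_starts[k + 1L] - 1L
      ilen <- ihi - ilo + 1L
      pe_len <- sample(seq(30L, min(150L, ilen - 10L)), 1L)
      pe_start <- sample(seq(ilo + 5L, ihi - 5L - pe_len + 1L), 1L)
      splice_event("pseudoexon_inclusion", pe_start = pe_start,
                   pe_end = pe_start + pe_len - 1L)
    },
    exon_skip = splice_event("exon_skip",
                             exon = if (length(elig) == 1L) elig
                                    else sample(elig, 1L)),
    exon_extension_5 = {
      k <- if (length(elig) == 1L) elig else sample(elig, 1L)
      ilen <- abs(if (minus) tx$exon_starts[k - 1L] - tx$exon_ends[k]
                  else tx$exon_starts[k] - tx$exon_ends[k - 1L]) - 1L
      splice_event("exon_extension_5", exon = k,
                   extension_nt = sample(seq(1L, min(60L, ilen - 5L)), 1L))
    },
    exon_extension_3 = {
      k <- if (length(elig) == 1L) elig else sample(elig, 1L)
      ilen <- abs(if (minus) tx$exon_starts[k] - tx$exon_ends[k + 1L]
                  else tx$exon_starts[k + 1L] - tx$exon_ends[k]) - 1L
      splice_event("exon_extension_3", exon = k,
                   extension_nt = sample(seq(1L, min(60L, ilen - 5L)), 1L))
    },
    partial_exon_skip = {
      k <- if (length(elig) == 1L) elig else sample(elig, 1L)
      n <- sample(seq(1L, tx$exon_lengths[k] - 10L), 1L)
      splice_event("partial_exon_skip", exon = k, deleted_nt = n,
                   side = sample(c("5", "3"), 1L))
    },
    exon_internal_deletion = {
      k <- if (length(elig) == 1L) elig else sample(elig, 1L)
      len <- tx$exon_lengths[k]
      keep5 <- sample(seq(5L, len - 11L), 1L)
      keep3 <- sample(seq(5L, len - keep5 - 1L), 1L)
      splice_event("exon_internal_deletion", exon = k,
                   novel_donor_offset = keep5, novel_acceptor_offset = keep3)
    })
  truth <- suppressWarnings(bf_splice_consequence(tx, ev))
  list(event = ev, truth = truth)
}

#' Generate a synthetic cohort with expected statuses
#'
#' Samples per-proband genotype categories from the mixture weights, draws
#' allele classifications accordingly, and derives the expected case status
#' from the enumerated reference table (never from [resolve_case()] itself).
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (data frame: id, causal_gene, variant1,
#'   class1, variant2, class2) and `expected_status` (character vector).
#' @export
make_cohort <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  n <- cfg$n_probands
  if (n == 0L)
    return(list(cohort = data.frame(id = character(0),
                                    causal_gene = character(0),
                                    variant1 = character(0),
                                    class1 = character(0),
                                    variant2 = character(0),
                                    class2 = character(0)),
                expected_status = character(0)))
  cats <- sample(names(cfg$mixture_weights), n, replace = TRUE,
                 prob = cfg$mixture_weights)
  plp <- c("pathogenic", "likely_pathogenic")
  soft <- c("benign", "likely_benign")
  draw <- function(cat) {
    switch(cat,
      plp_pair = c(sample(plp, 1L), sample(plp, 1L)),
      plp_vus = sample(c(sample(plp, 1L), "vus")),
      vus_vus = c("vus", "vus"),
      benign_pair = sample(c(sample(soft, 1L),
                             sample(c(soft, "vus", plp), 1L))),
      mono = c(sample(CLASSIFICATION_LEVELS, 1L), NA_character_),
      none = c(NA_character_, NA_character_))
  }
  pairs <- t(vapply(cats, draw, character(2)))
  phe <- sample(c("arRP", "USH", "DFNB", "CRD"), n, replace = TRUE,
                prob = c(0.47, 0.49, 0.03, 0.01))
  ids <- paste0(phe, 100L + seq_len(n))
  rvar <- function(cl) ifelse(is.na(cl), NA_character_,
                              paste0("c.", sample(9000L, length(cl),
                                                  replace = TRUE), "A>G"))
  cohort <- data.frame(id = ids, causal_gene = "USH2A",
                       variant1 = rvar(pairs[, 1]), class1 = pairs[, 1],
                       variant2 = rvar(pairs[, 2]), class2 = pairs[, 2],
                       stringsAsFactors = FALSE)
  cohort$causal_gene[is.na(pairs[, 1]) & is.na(pairs[, 2])] <- NA_character_
  oracle <- resolve_case_oracle_table()
  key <- function(a, b) paste(ifelse(is.na(a), ".", a),
                              ifelse(is.na(b), ".", b))
  lut <- stats::setNames(oracle$status, key(oracle$class1, oracle$class2))
  expected <- unname(lut[key(pairs[, 1], pairs[, 2])])
  list(cohort = cohort, expected_status = expected)
}

#' Generate an annotated variant table
#'
#' Annotation fields are sampled independently per variant (sufficient for
#' exercising threshold logic; not biologically correlated): categories
#' uniform over the SNV classes, allele frequencies log-uniform-ish with a
#' spike at 0, Grantham 5-215, CADD 0-60, PhyloP -5-10, SpliceAI deltas
#' mostly small with occasional high scores.
#'
#' @param cfg a [sim_config()]; `n_variants` rows are produced.
#' @param tx optional [transcript_model]; variant positions are then drawn
#'   within its genomic span (otherwise within an arbitrary window).
#' @return data frame with columns chrom, pos, ref, alt, category,
#'   af_global, af_subpops, grantham, cadd_phred, phylop, ds_ag, ds_al,
#'   ds_dg, ds_dl.
#' @export
make_variant_table <- function(cfg = sim_config(), tx = NULL) {
  maybe_seed(cfg)
  n <- cfg$n_variants
  span <- if (!is.null(tx))
    c(min(tx$exon_starts), max(tx$exon_ends))
  else c(cfg$genome_start, cfg$genome_start + 100000L)
  pos <- sort(sample(seq(span[1], span[2]), n, replace = FALSE))
  base <- c("A", "C", "G", "T")
  ref <- sample(base, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(base, r), 1L), "")
  af <- ifelse(stats::runif(n) < 0.3, 0,
               signif(10^stats::runif(n, -5, -0.3), 3))
  subp <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1L)
    if (k == 0) "" else paste(signif(pmin(1, af[i] * 10^stats::runif(k, -0.5, 0.7)), 3),
                              collapse = ",")
  }, "")
  ds <- function() ifelse(stats::runif(n) < 0.2,
                          round(stats::runif(n, 0.1, 1), 2),
                          round(stats::runif(n, 0, 0.09), 2))
  data.frame(
    chrom = rep(if (!is.null(tx)) tx$chrom else "chrS", n),
    pos = pos, ref = ref, alt = alt,
    category = sample(SNV_CATEGORIES, n, replace = TRUE),
    af_global = af, af_subpops = subp,
    grantham = round(stats::runif(n, 5, 215)),
    cadd_phred = round(stats::runif(n, 0, 60), 1),
    phylop = round(stats::runif(n, -5, 10), 2),
    ds_ag = ds(), ds_al = ds(), ds_dg = ds(), ds_dl = ds(),
    stringsAsFactors = FALSE)
}
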