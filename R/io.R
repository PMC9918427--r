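# Readers and writers: VCF extraction via VariantAnnotation, BED via
# rtracklayer (0-based half-open on disk, 1-based inclusive in memory),
# simple TSV schemas for annotated variants, assay outcomes and regions, and
# accessors for the packaged study fixtures.

VCF_INFO_KEYS <- list(af = "AF", subpops = "AF_POPS", category = "CAT",
                      grantham = "GRANTHAM", cadd = "CADD", phylop = "PHYLOP",
                      spliceai = "SAI")

#' Write an annotated variant table as VCF 4.2
#'
#' Emits the synthetic annotation bundle under INFO keys `AF`, `AF_POPS`
#' (comma string), `CAT`, `GRANTHAM`, `CADD`, `PHYLOP` and the four SpliceAI
#' delta scores pipe-delimited under `SAI` (DS_AG|DS_AL|DS_DG|DS_DL).
#'
#' @param variants data frame as from [make_variant_table()].
#' @param path output file (plain text, uncompressed).
#' @param sample_name sample column name.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(variants, path, sample_name = "SYN1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=splicedx-synthetic",
    sprintf("##contig=<ID=%s>", unique(variants$chrom)),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Global allele frequency\">",
    "##INFO=<ID=AF_POPS,Number=.,Type=Float,Description=\"Subpopulation allele frequencies\">",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Consequence category\">",
    "##INFO=<ID=GRANTHAM,Number=1,Type=Float,Description=\"Grantham score\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD PHRED score\">",
    "##INFO=<ID=PHYLOP,Number=1,Type=Float,Description=\"PhyloP score\">",
    "##INFO=<ID=SAI,Number=1,Type=String,Description=\"SpliceAI delta scores DS_AG|DS_AL|DS_DG|DS_DL\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- c(sprintf("AF=%s", v$af_global),
              if (nzchar(v$af_subpops)) sprintf("AF_POPS=%s", v$af_subpops),
              sprintf("CAT=%s", v$category),
              sprintf("GRANTHAM=%s", v$grantham),
              sprintf("CADD=%s", v$cadd_phred),
              sprintf("PHYLOP=%s", v$phylop),
              sprintf("SAI=%s|%s|%s|%s", v$ds_ag, v$ds_al, v$ds_dg, v$ds_dl))
    paste(v$chrom, v$pos, ".", v$ref, v$alt, "100", "PASS",
          paste(info, collapse = ";"), "GT", "0/1", sep = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Extract annotated variants overlapping target regions from a VCF
#'
#' Reads a VCF 4.2 file (multi-allelic records are decomposed into per-alt
#' variants), keeps records overlapping the regions, parses the annotation
#' INFO keys (missing keys leave NA scores; the record is kept), and returns
#' them in deterministic order (position, then alt allele).
#'
#' @param vcf_path VCF file.
#' @param regions a [GenomicRanges::GRanges] of target regions (1-based
#'   inclusive), or NULL for no region filter.
#' @param info_keys named list overriding the default INFO key names.
#' @return data frame in the [make_variant_table()] schema.
#' @export
extract_region_variants <- function(vcf_path, regions = NULL,
                                    info_keys = VCF_INFO_KEYS) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  vcf <- VariantAnnotation::expand(vcf)   # decompose multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- if (is.null(regions)) seq_along(rr)
          else S4Vectors::queryHits(GenomicRanges::findOverlaps(rr, regions))
  keep <- sort(unique(keep))
  if (length(keep) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      category = character(0), af_global = numeric(0),
                      af_subpops = character(0), grantham = numeric(0),
                      cadd_phred = numeric(0), phylop = numeric(0),
                      ds_ag = numeric(0), ds_al = numeric(0),
                      ds_dg = numeric(0), ds_dl = numeric(0)))
  vcf <- vcf[keep]
  rr <- rr[keep]
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  get1 <- function(key, default = NA_real_) {
    if (is.null(key) || !key %in% colnames(info)) return(rep(default, n))
    x <- info[[key]]
    if (methods::is(x, "List") || is.list(x))
      x <- vapply(x, function(e) if (length(e)) e[[1]] else default,
                  default)
    x
  }
  subpops <- if (!is.null(info_keys$subpops) &&
                 info_keys$subpops %in% colnames(info)) {
    vapply(info[[info_keys$subpops]], function(e)
      paste(as.numeric(e), collapse = ","), "")
  } else rep("", n)
  sai <- get1(info_keys$spliceai, NA_character_)
  ds <- t(vapply(sai, function(s) {
    if (is.na(s)) return(rep(NA_real_, 4))
    parts <- suppressWarnings(as.numeric(strsplit(s, "|", fixed = TRUE)[[1]]))
    if (length(parts) != 4) rep(NA_real_, 4) else parts
  }, numeric(4)))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    category = as.character(get1(info_keys$category, NA_character_)),
    af_global = as.numeric(get1(info_keys$af)),
    af_subpops = subpops,
    grantham = as.numeric(get1(info_keys$grantham)),
    cadd_phred = as.numeric(get1(info_keys$cadd)),
    phylop = as.numeric(get1(info_keys$phylop)),
    ds_ag = ds[, 1], ds_al = ds[, 2], ds_dg = ds[, 3], ds_dl = ds[, 4],
    stringsAsFactors = FALSE)
  out[order(out$pos, out$alt), , drop = FALSE]
}

#' Read target regions from a BED file
#'
#' BED files are 0-based half-open on disk; [rtracklayer::import()] converts
#' them to the in-memory 1-based inclusive convention.
#'
#' @param path BED file.
#' @return a [GenomicRanges::GRanges].
#' @export
read_bed_regions <- function(path) rtracklayer::import(path, format = "BED")

#' Write genomic regions as BED
#'
#' @param regions data frame with chrom, start, end (1-based inclusive) or a
#'   GRanges.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  if (inherits(regions, "GRanges")) {
    rtracklayer::export(regions, path, format = "BED")
  } else {
    writeLines(sprintf("%s\t%d\t%d", regions$chrom,
                       as.integer(regions$start) - 1L,
                       as.integer(regions$end)), path)
  }
  invisible(path)
}

#' Read a gene panel (one symbol per line, '#' comments allowed)
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# ---- assay outcome table (events encoded as text) --------------------------

parse_event_spec <- function(spec) {
  # grammar: type:args, e.g. "pseudoexon_inclusion:chr1:216495824-216495941",
  # "exon_skip:28", "exon_extension_5:47@65", "partial_exon_skip:153@46:3",
  # "exon_internal_deletion:129,115@13"
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  type <- parts[1]
  arg <- paste(parts[-1], collapse = ":")
  if (type == "pseudoexon_inclusion") {
    m <- regmatches(arg, regexec("^(?:([^:]+):)?([0-9]+)-([0-9]+)$", arg))[[1]]
    if (length(m) == 0) stop("bad pseudoexon spec: ", spec)
    return(splice_event("pseudoexon_inclusion",
                        pe_start = as.integer(m[3]), pe_end = as.integer(m[4])))
  }
  if (type == "exon_skip")
    return(splice_event("exon_skip", exon = as.integer(arg)))
  if (type %in% c("exon_extension_5", "exon_extension_3")) {
    m <- regmatches(arg, regexec("^([0-9]+)@([0-9]+)$", arg))[[1]]
    return(splice_event(type, exon = as.integer(m[3]),
                        extension_nt = as.integer(m[2])))
  }
  if (type == "partial_exon_skip") {
    m <- regmatches(arg, regexec("^([0-9]+)@([0-9]+)(?::([53]))?$", arg,
                                 perl = TRUE))[[1]]
    return(splice_event("partial_exon_skip", exon = as.integer(m[3]),
                        deleted_nt = as.integer(m[2]),
                        side = if (nzchar(m[4])) m[4] else "3"))
  }
  if (type == "exon_internal_deletion") {
    m <- regmatches(arg, regexec("^([0-9]+),([0-9]+)@([0-9]+)$", arg))[[1]]
    return(splice_event("exon_internal_deletion", exon = as.integer(m[4]),
                        novel_donor_offset = as.integer(m[2]),
                        novel_acceptor_offset = as.integer(m[3])))
  }
  stop("unknown event type in spec: ", spec)
}

#' Read an assay outcome table
#'
#' TSV with columns `variant`, `variant_class` (deep_intronic,
#' noncanonical_splice, exonic, branchpoint), `effect` (none/partial/full),
#' `events` (`;`-separated event specs, e.g.
#' `"pseudoexon_inclusion:chr1:216495824-216495941"`, `"exon_skip:28"`,
#' `"exon_extension_5:47@65"`, `"partial_exon_skip:153@46"`,
#' `"exon_internal_deletion:129,115@13"`), `effect_classes` (comma list of
#' protein effect classes per event), `consequence_p` (printed protein
#' notation), `domain_disrupted` (0/1), `proband`.
#'
#' @param path TSV file; defaults to the packaged minigene outcome fixture.
#' @return data frame; the parsed events are attached as a list column
#'   `event_list`.
#' @export
read_outcome_table <- function(path = splicedx_fixture("assay_outcomes.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$event_list <- lapply(df$events, function(e) {
    if (is.na(e) || !nzchar(e)) list()
    else lapply(strsplit(e, ";", fixed = TRUE)[[1]], parse_event_spec)
  })
  df
}

#' Path to a packaged study fixture
#'
#' @param name file name under the package's `extdata` (e.g.
#'   `"study_cohort.tsv"`, `"splice_candidates.tsv"`,
#'   `"assay_outcomes.tsv"`, `"pseudoexons.tsv"`).
#' @return absolute path.
#' @export
splicedx_fixture <- function(name) {
  p <- system.file("extdata", name, package = "splicedx")
  if (!nzchar(p)) stop("no packaged fixture named ", name)
  p
}
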