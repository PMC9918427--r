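# Cohort table handling: the 100-proband table (two classified alleles per
# subject), case resolution, solve-rate summaries and structural-variant
# accounting.

COHORT_COLUMNS <- c("id", "causal_gene", "variant1", "protein1", "class1",
                    "vus_causative1", "variant2", "protein2", "class2",
                    "vus_causative2", "in_trans", "status_printed")

#' Read a proband cohort table
#'
#' Tab-separated with columns `id`, `causal_gene`, `variant1`, `protein1`,
#' `class1`, `vus_causative1`, `variant2`, `protein2`, `class2`,
#' `vus_causative2`, `in_trans`, `status_printed`. Empty cells mean a
#' missing allele. The `status_printed` column is the published verdict and
#' is never consulted by [resolve_case()]; it is retained for validation
#' only. The phenotype is derived from the id prefix
#' (arRP/USH/DFNB/CRD).
#'
#' @param path TSV file.
#' @return data frame with an added `phenotype` column.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(setdiff(COHORT_COLUMNS, c("status_printed")), names(df))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  df$phenotype <- proband_phenotype(df$id)
  df
}

#' Phenotype from a proband identifier prefix
#'
#' @param id character vector of proband ids (e.g. `"arRP10"`, `"USH46"`).
#' @return character vector over arRP/USH/DFNB/CRD.
#' @export
proband_phenotype <- function(id) {
  m <- regmatches(id, regexpr("^(arRP|USH|DFNB|CRD)", id))
  if (length(m) != length(id))
    stop("proband id(s) without a recognised phenotype prefix")
  m
}

#' Resolve every case in a cohort
#'
#' @param cohort data frame as from [read_cohort_tsv()].
#' @return the cohort with an added `status` column.
#' @export
resolve_cohort <- function(cohort) {
  flag <- function(x) if (is.null(x)) rep(TRUE, nrow(cohort))
                      else !(as.integer(ifelse(is.na(x), 1L, x)) == 0L)
  vc1 <- flag(cohort$vus_causative1)
  vc2 <- flag(cohort$vus_causative2)
  cohort$status <- vapply(seq_len(nrow(cohort)), function(i)
    resolve_case(cohort$class1[i], cohort$class2[i], vc1[i], vc2[i]), "")
  cohort
}

round_half_up <- function(x) floor(x + 0.5)

#' Cohort solve-rate summary
#'
#' Counts and integer-rounded percentages of resolved (solved + possibly
#' solved) cases overall, per phenotype, and per causal-gene group (the
#' primary gene versus other panel genes).
#'
#' @param cohort data frame with a `status` column (see [resolve_cohort()];
#'   computed here when absent).
#' @param primary_gene gene symbol anchoring the gene split (default
#'   `"USH2A"`).
#' @return list with elements `overall` (n, solved, possibly_solved,
#'   resolved, pct_resolved), `by_phenotype` (data frame), `by_gene`
#'   (resolved counts for the primary gene and others).
#' @export
cohort_summary <- function(cohort, primary_gene = "USH2A") {
  if (nrow(cohort) == 0)
    return(list(overall = list(n = 0L, solved = 0L, possibly_solved = 0L,
                               resolved = 0L, pct_resolved = 0),
                by_phenotype = data.frame(phenotype = character(0),
                                          n = integer(0),
                                          resolved = integer(0),
                                          pct_resolved = numeric(0)),
                by_gene = list()))
  if (is.null(cohort$status)) cohort <- resolve_cohort(cohort)
  if (is.null(cohort$phenotype)) cohort$phenotype <- proband_phenotype(cohort$id)
  resolved <- cohort$status %in% c("solved", "possibly_solved")
  overall <- list(
    n = nrow(cohort),
    solved = sum(cohort$status == "solved"),
    possibly_solved = sum(cohort$status == "possibly_solved"),
    resolved = sum(resolved),
    pct_resolved = round_half_up(100 * sum(resolved) / nrow(cohort)))
  phes <- unique(cohort$phenotype)
  by_phenotype <- do.call(rbind, lapply(phes, function(ph) {
    sel <- cohort$phenotype == ph
    data.frame(phenotype = ph, n = sum(sel), resolved = sum(resolved & sel),
               pct_resolved = round_half_up(100 * sum(resolved & sel) /
                                            sum(sel)))
  }))
  gene <- ifelse(is.na(cohort$causal_gene) | cohort$causal_gene == "",
                 NA_character_, cohort$causal_gene)
  by_gene <- list(
    primary = sum(resolved & !is.na(gene) & gene == primary_gene),
    other = sum(resolved & !is.na(gene) & gene != primary_gene))
  names(by_gene)[1] <- primary_gene
  list(overall = overall, by_phenotype = by_phenotype, by_gene = by_gene)
}

#' Structural-variant accounting over a cohort
#'
#' Collects the alleles attributed to `gene` (variants in probands without a
#' listed causal gene default to the primary gene under study), keeps those
#' that are structural (span >= `min_size` nt or inversions, from the HGVS
#' description), and tallies unique variants (by normalised HGVS string),
#' allele occurrences, and per-type counts via [sv_type_from_hgvs()].
#'
#' @param cohort data frame as from [read_cohort_tsv()].
#' @param gene gene whose SVs are counted (default `"USH2A"`).
#' @param min_size SV size convention (default 50 nt).
#' @return list with `n_unique`, `n_alleles`, `by_type` (named integer
#'   vector) and `variants` (data frame of normalised HGVS, type, allele
#'   count).
#' @export
count_sv_alleles <- function(cohort, gene = "USH2A", min_size = 50L) {
  alleles <- character(0)
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$causal_gene[i]
    vgene <- if (is.na(g) || g == "") gene else g
    if (vgene != gene) next
    for (col in c("variant1", "variant2")) {
      v <- cohort[[col]][i]
      if (!is.na(v) && nzchar(v)) alleles <- c(alleles, v)
    }
  }
  parsed <- lapply(alleles, parse_hgvs)
  sv <- vapply(parsed, is_structural, TRUE, min_size = min_size)
  parsed <- parsed[sv]
  if (length(parsed) == 0)
    return(list(n_unique = 0L, n_alleles = 0L,
                by_type = integer(0),
                variants = data.frame(hgvs = character(0), type = character(0),
                                      alleles = integer(0))))
  norm <- vapply(parsed, format_hgvs, "")
  type <- vapply(parsed, sv_type_from_hgvs, "")
  tab <- table(norm)
  uniq <- names(tab)
  utype <- type[match(uniq, norm)]
  list(n_unique = length(uniq),
       n_alleles = length(norm),
       by_type = table(utype),
       variants = data.frame(hgvs = uniq, type = utype,
                             alleles = as.integer(tab),
                             row.names = NULL))
}
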