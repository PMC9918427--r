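# Pipeline composition: extract -> AF filter -> triage -> assay selection ->
# consequence -> classify -> resolve -> summarise, with every output written
# to the configured directory and every applied threshold logged.

#' Pipeline configuration
#'
#' Collects input paths and triage settings. All inputs are optional: a
#' stage whose inputs are absent writes an empty but schema-valid output.
#' The configuration round-trips through YAML via
#' [read_pipeline_config()]/[write_pipeline_config()].
#'
#' @param vcf path to an annotated VCF (SNVs).
#' @param regions_bed BED file of target regions.
#' @param transcript_tsv,transcript_fasta transcript model and its genomic
#'   sequence.
#' @param cohort_tsv proband cohort table.
#' @param outcomes_tsv minigene outcome table.
#' @param candidates_tsv splice-candidate table with exclusion flags.
#' @param out_dir output directory (created when missing).
#' @param triage a [triage_config()] or a named list of its arguments.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, regions_bed = NULL,
                            transcript_tsv = NULL, transcript_fasta = NULL,
                            cohort_tsv = NULL, outcomes_tsv = NULL,
                            candidates_tsv = NULL, out_dir = "splicedx-out",
                            triage = triage_config(), log_level = "info") {
  if (is.list(triage) && !inherits(triage, "triage_config"))
    triage <- do.call(triage_config, triage)
  structure(list(vcf = vcf, regions_bed = regions_bed,
                 transcript_tsv = transcript_tsv,
                 transcript_fasta = transcript_fasta,
                 cohort_tsv = cohort_tsv, outcomes_tsv = outcomes_tsv,
                 candidates_tsv = candidates_tsv, out_dir = out_dir,
                 triage = triage, log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tri <- y$triage %||% list()
  y$triage <- NULL
  do.call(pipeline_config, c(y, list(triage = tri)))
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$triage <- unclass(y$triage)[c("af_max", "grantham_min", "cadd_min",
                                  "phylop_min", "spliceai_single_min",
                                  "spliceai_pair_min", "sv_quality_min")]
  y <- Filter(Negate(is.null), y)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the interpretation pipeline
#'
#' Composes the stages in order: extract variants over the target regions,
#' apply the allele-frequency filter and triage criteria, select splice
#' candidates for assay, compute protein consequences for assayed outcomes
#' (when a transcript with sequence is available), classify from assay
#' outcomes, resolve the cohort and summarise. Writes `triage.tsv`,
#' `consequences.tsv`, `proband_status.tsv`, `cohort_summary.json` and
#' `pipeline.log` under the output directory; re-running on identical inputs
#' is byte-identical apart from the log timestamp. Any stage failure aborts
#' with an error naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with the computed tables and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- c(sprintf("# splicedx pipeline log (%s)",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))
  tri <- cfg$triage
  log("thresholds: af_max=%g grantham_min=%g cadd_min=%g phylop_min=%g",
      tri$af_max, tri$grantham_min, tri$cadd_min, tri$phylop_min)
  log("thresholds: spliceai_single_min=%g spliceai_pair_min=%g sv_quality_min=%g",
      tri$spliceai_single_min, tri$spliceai_pair_min, tri$sv_quality_min)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- extract + triage
  triaged <- stage("extract/triage", {
    if (!is.null(cfg$vcf)) {
      regions <- if (!is.null(cfg$regions_bed)) read_bed_regions(cfg$regions_bed)
      variants <- extract_region_variants(cfg$vcf, regions)
      log("extracted %d variant records", nrow(variants))
      tv <- triage_variants(variants, tri)
      log("AF filter retained %d of %d; triage retained %d",
          sum(tv$af_pass), nrow(tv), sum(tv$retained))
      tv
    } else {
      log("no VCF configured; triage table empty")
      triage_variants(make_variant_table(sim_config(seed = NA,
                                                    n_variants = 0L)), tri)
    }
  })
  triage_path <- file.path(cfg$out_dir, "triage.tsv")
  utils::write.table(triaged, triage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- assay selection
  selected <- stage("assay-selection", {
    if (!is.null(cfg$candidates_tsv)) {
      cand <- utils::read.delim(cfg$candidates_tsv, stringsAsFactors = FALSE)
      sel <- select_for_minigene(cand)
      log("minigene selection: %d of %d candidates retained",
          nrow(sel), nrow(cand))
      sel
    } else NULL
  })

  # -- consequences for assayed outcomes
  consequences <- stage("consequence", {
    tx <- NULL
    if (!is.null(cfg$transcript_tsv))
      tx <- read_transcript_tsv(cfg$transcript_tsv, cfg$transcript_fasta)
    if (!is.null(cfg$outcomes_tsv)) {
      out_tab <- read_outcome_table(cfg$outcomes_tsv)
      rows <- lapply(seq_len(nrow(out_tab)), function(i) {
        evs <- out_tab$event_list[[i]]
        classes <- if (!is.na(out_tab$effect_classes[i]))
          strsplit(out_tab$effect_classes[i], ",", fixed = TRUE)[[1]]
        else character(0)
        predicted <- if (!is.null(tx) && !is.null(tx$genome_seq) &&
                         length(evs) > 0) {
          oc <- splice_outcome(out_tab$variant[i], evs,
                               out_tab$effect[i] == "partial")
          format_consequences(consequence_for_outcome(tx, oc))
        } else NA_character_
        cls <- classify_from_assay(
          effect_classes = classes,
          conventional_present = out_tab$effect[i] %in% c("partial", "none"),
          domain_disrupted = isTRUE(out_tab$domain_disrupted[i] == 1))
        data.frame(variant = out_tab$variant[i],
                   effect = out_tab$effect[i],
                   n_events = length(evs),
                   predicted_p = predicted,
                   assay_classification = cls$label %||% NA_character_,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      log("consequences computed for %d assayed variants", nrow(tab))
      tab
    } else {
      log("no outcome table configured; consequence table empty")
      data.frame(variant = character(0), effect = character(0),
                 n_events = integer(0), predicted_p = character(0),
                 assay_classification = character(0))
    }
  })
  cons_path <- file.path(cfg$out_dir, "consequences.tsv")
  utils::write.table(consequences, cons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- resolve + summarise
  res <- stage("resolve/summarise", {
    if (!is.null(cfg$cohort_tsv)) {
      cohort <- resolve_cohort(read_cohort_tsv(cfg$cohort_tsv))
      summ <- cohort_summary(cohort)
      svs <- count_sv_alleles(cohort)
      log("cohort: %d probands, %d resolved (%d%%)", summ$overall$n,
          summ$overall$resolved, summ$overall$pct_resolved)
      list(cohort = cohort, summary = summ, svs = svs)
    } else {
      log("no cohort configured; status table empty")
      list(cohort = data.frame(id = character(0), status = character(0)),
           summary = cohort_summary(data.frame()[0, , drop = FALSE]),
           svs = NULL)
    }
  })
  status_path <- file.path(cfg$out_dir, "proband_status.tsv")
  status_cols <- intersect(c("id", "phenotype", "causal_gene", "class1",
                             "class2", "status"), names(res$cohort))
  utils::write.table(res$cohort[, status_cols, drop = FALSE], status_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_path <- file.path(cfg$out_dir, "cohort_summary.json")
  summ_out <- res$summary
  if (!is.null(res$svs))
    summ_out$sv_accounting <- list(n_unique = res$svs$n_unique,
                                   n_alleles = res$svs$n_alleles,
                                   by_type = as.list(res$svs$by_type))
  if (!is.null(selected))
    summ_out$minigene_selected <- nrow(selected)
  jsonlite::write_json(summ_out, summary_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  writeLines(log_lines, log_path)

  invisible(list(triage = triaged, selected = selected,
                 consequences = consequences, cohort = res$cohort,
                 summary = summ_out,
                 paths = c(triage = triage_path, consequences = cons_path,
                           status = status_path, summary = summary_path,
                           log = log_path)))
}
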