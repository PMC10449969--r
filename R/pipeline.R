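#' Candidate-mutation report for burden-significant genes
#'
#' Tabulates the prioritized variants that fall in genes significant under
#' either inheritance model of a burden scan (union of the two models: a
#' gene credible under only one model is still a candidate), one row per
#' surviving carrier call, with the functional scores the pipeline consumes.
#' When a gene-by-tissue expression table is supplied the report is ranked
#' by mean expression across tissues, highest first — the working assumption
#' being that a candidate for a tissue-restricted phenotype should at least
#' be expressed there.
#'
#' @param burden a `burden_scan` result.
#' @param prioritized a `prioritized_set`.
#' @param expression optional data.frame: column `gene` plus one numeric
#'   column per tissue. Genes absent from the table get `NA` rank, not an
#'   error.
#' @return data.frame, one row per candidate call: gene, variant_id,
#'   sample_id, zygosity, scores, sig_dom/sig_rec flags, mean_expression
#'   and expression_rank when available.
#' @export
candidate_report <- function(burden, prioritized, expression = NULL) {
  sig <- burden$gene[burden$sig_dom | burden$sig_rec]
  pairs <- prioritized$pairs
  out <- pairs[pairs$gene %in% sig, , drop = FALSE]
  cols <- c("gene", "variant_id", "sample_id", "zygosity", "sift",
            "polyphen", "mutation_taster", "predictsnp2_benign", "maf",
            "allele_ratio")
  out <- out[, intersect(cols, names(out)), drop = FALSE]
  out$sig_dom <- burden$sig_dom[match(out$gene, burden$gene)]
  out$sig_rec <- burden$sig_rec[match(out$gene, burden$gene)]
  if (!is.null(expression)) {
    num <- vapply(expression, is.numeric, logical(1))
    mean_expr <- rowMeans(expression[, num, drop = FALSE], na.rm = TRUE)
    out$mean_expression <- mean_expr[match(out$gene, expression$gene)]
    out$expression_rank <- rank(-out$mean_expression, ties.method = "min",
                                na.last = "keep")
    out <- out[order(out$mean_expression, decreasing = TRUE,
                     na.last = TRUE), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

pipeline_config_defaults <- function() {
  list(vcf = NULL, controls = NULL, gmt = NULL, background = NULL,
       expression = NULL, out_dir = ".",
       control_n = 125748L, alpha = 0.05,
       maf_max = 0.001, ar_het_low = 0.35, ar_het_high = 0.65,
       ar_hom_min = 0.9, recurrence_max = 5L,
       burden_maf_max = 0.01, burden_min_depth = 10L,
       burden_sift_max = 0.05, burden_polyphen_min = 0.8,
       recessive_strategy = "reported_hom",
       burden_genes = "top_terms", n_top_terms = 1L,
       seed = NULL)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  for (field in c("vcf", "controls", "gmt"))
    if (is.null(cfg[[field]]))
      stop("pipeline config missing required field '", field, "'",
           call. = FALSE)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full inference chain
#'
#' Stages: load the cohort and control summary; prioritize variants
#' (functional/MAF cascade, allele-ratio QC, recurrence filter); scan the
#' collapsed gene list for overrepresented gene sets; run the burden test on
#' the genes of the top significant term(s) (or on all genes; if no term
#' reaches significance the scan also falls back to all genes); and emit
#' the candidate-mutation report. All stage outputs are written as TSV under
#' `out_dir` together with a JSON run manifest recording inputs, thresholds
#' and package version.
#'
#' @param config path to a YAML file or an equivalent named list. Required
#'   fields: `vcf`, `controls`, `gmt`. Optional: `background` (newline-
#'   delimited gene universe; defaults to all genes in the GMT),
#'   `expression` (TSV with a `gene` column plus numeric tissue columns),
#'   `out_dir`, `control_n`, `alpha`, prioritization thresholds (`maf_max`,
#'   `ar_het_low`, `ar_het_high`, `ar_hom_min`, `recurrence_max`), burden
#'   thresholds (`burden_maf_max`, `burden_min_depth`, `burden_sift_max`,
#'   `burden_polyphen_min`), `recessive_strategy`, `burden_genes`
#'   (`"top_terms"` or `"all"`), `n_top_terms`, `seed` (recorded in the
#'   manifest; the pipeline itself is deterministic).
#' @return invisibly, a list with the in-memory stage results:
#'   `prioritized`, `enrichment`, `burden`, `candidates`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("read_cohort", read_cohort_vcf(cfg$vcf))
  controls <- stage("read_controls", read_control_summary(cfg$controls))

  criteria <- prioritization_criteria(
    maf_max_snv = cfg$maf_max, maf_max_indel = cfg$maf_max,
    recurrence_max = cfg$recurrence_max)
  bounds <- ar_bounds(cfg$ar_het_low, cfg$ar_het_high, cfg$ar_hom_min)
  prioritized <- stage("prioritize", prioritize(cohort, criteria, bounds))
  write_prioritized(prioritized,
                    pairs_path = file.path(cfg$out_dir, "prioritized.tsv"),
                    genes_path = file.path(cfg$out_dir, "gene_list.txt"),
                    attrition_path = file.path(cfg$out_dir,
                                               "attrition.tsv"))

  background <- if (is.null(cfg$background)) NULL else
    readLines(cfg$background)
  collection <- stage("read_gene_sets", {
    bg <- if (is.null(background)) {
      lines <- strsplit(readLines(cfg$gmt), "\t", fixed = TRUE)
      unique(unlist(lapply(lines, function(p) p[-(1:2)])))
    } else background
    read_gene_sets(cfg$gmt, bg)
  })
  enr_list <- intersect(prioritized$genes, collection$background)
  enrichment <- stage("enrichment",
                      run_enrichment(enr_list, collection,
                                     alpha = cfg$alpha))
  utils::write.table(as.data.frame(enrichment),
                     file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_subset <- if (identical(cfg$burden_genes, "all")) NULL else {
    top <- enrichment[enrichment$significant, , drop = FALSE]
    top <- top[seq_len(min(cfg$n_top_terms, nrow(top))), , drop = FALSE]
    if (nrow(top) == 0L) NULL else   # no significant term: scan all genes
      unique(unlist(lapply(top$term_id,
                           function(id) collection$terms[[id]]$genes)))
  }
  qcrit <- qualifying_criteria(min_depth = cfg$burden_min_depth,
                               sift_max = cfg$burden_sift_max,
                               polyphen_min = cfg$burden_polyphen_min,
                               maf_max = cfg$burden_maf_max)
  burden <- stage("burden",
                  run_burden_scan(cohort, controls,
                                  control_n = cfg$control_n,
                                  gene_subset = gene_subset,
                                  criteria = qcrit,
                                  recessive_strategy =
                                    cfg$recessive_strategy,
                                  alpha = cfg$alpha))
  utils::write.table(as.data.frame(burden),
                     file.path(cfg$out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  expression <- if (is.null(cfg$expression)) NULL else
    utils::read.table(cfg$expression, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  candidates <- stage("report",
                      candidate_report(burden, prioritized, expression))
  utils::write.table(candidates,
                     file.path(cfg$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    stages = c("prioritize", "enrich", "burden", "report"),
    inputs = cfg[c("vcf", "controls", "gmt", "background", "expression")],
    thresholds = cfg[c("maf_max", "ar_het_low", "ar_het_high",
                       "ar_hom_min", "recurrence_max", "burden_maf_max",
                       "burden_min_depth", "burden_sift_max",
                       "burden_polyphen_min", "alpha",
                       "recessive_strategy")],
    n_cases = n_cases(cohort),
    control_n = cfg$control_n,
    burden_gene_subset_size = if (is.null(gene_subset)) NA_integer_
                              else length(gene_subset),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("varburden")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(prioritized = prioritized, enrichment = enrichment,
                 burden = burden, candidates = candidates,
                 manifest = manifest))
}

#' Write a simulated study to disk
#'
#' Convenience wrapper for the command-line `simulate` subcommand: generates
#' a cohort, its matching control summary and a gene-set collection with a
#' spiked term drawn from the enriched genes, and writes `cases.vcf`,
#' `controls.tsv`, `sets.gmt` and `truth.json` under `out_dir`.
#'
#' @param spec a [cohort_sim_spec()].
#' @param out_dir output directory (created if needed).
#' @param n_terms random terms in the simulated collection.
#' @return invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(spec, out_dir, n_terms = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(spec)
  ctrl <- simulate_control_summary(spec)
  genes <- sort(unique(sim$truth$genes$gene))
  spiked <- sim$truth$genes$gene[sim$truth$genes$model != "null"]
  sets <- simulate_gene_sets(genes, n_terms = n_terms,
                             spiked_genes = if (length(spiked)) spiked
                                            else NULL,
                             seed = spec$seed + 2L)
  paths <- list(vcf = file.path(out_dir, "cases.vcf"),
                controls = file.path(out_dir, "controls.tsv"),
                gmt = file.path(out_dir, "sets.gmt"),
                truth = file.path(out_dir, "truth.json"))
  write_cohort_vcf(sim$cohort, paths$vcf)
  write_control_summary(ctrl, paths$controls)
  write_gene_sets(sets$collection, paths$gmt)
  jsonlite::write_json(list(variants = sim$truth$variants,
                            genes = sim$truth$genes,
                            terms = sets$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
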