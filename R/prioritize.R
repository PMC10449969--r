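#' Allele-ratio bounds for genotype QC
#'
#' The allele ratio AR = alt reads / depth flags artifactual calls: a true
#' heterozygote should sit near 0.5, a true homozygote near 1. Defaults are
#' the conventional band for amplicon exome data: het calls kept for
#' 0.35 <= AR <= 0.65, homozygous calls for AR >= 0.9, all bounds inclusive.
#'
#' @param het_low,het_high inclusive AR band for heterozygous calls.
#' @param hom_min inclusive minimum AR for homozygous-alt calls.
#' @return object of class `ar_bounds`.
#' @export
ar_bounds <- function(het_low = 0.35, het_high = 0.65, hom_min = 0.9) {
  stopifnot(0 < het_low, het_low < het_high, het_high < hom_min,
            hom_min <= 1)
  structure(list(het_low = het_low, het_high = het_high, hom_min = hom_min),
            class = "ar_bounds")
}

#' Compute the allele ratio of a call
#'
#' @param alt_reads non-negative alternate-allele read count.
#' @param depth positive total coverage at the site.
#' @return `alt_reads / depth`, vectorized.
#' @export
allele_ratio <- function(alt_reads, depth) {
  if (any(depth <= 0))
    stop("allele ratio undefined at zero depth; call cannot be QC'd",
         call. = FALSE)
  if (any(alt_reads < 0) || any(alt_reads > depth))
    stop("alt_reads must lie in [0, depth]", call. = FALSE)
  alt_reads / depth
}

#' Allele-ratio QC predicate
#'
#' @param zygosity `"het"` or `"hom_alt"`, vectorized.
#' @param alt_reads,depth read support of each call.
#' @param bounds an [ar_bounds()].
#' @return logical: whether each call passes the allelic-balance band.
#' @export
passes_allele_ratio <- function(zygosity, alt_reads, depth,
                                bounds = ar_bounds()) {
  stopifnot(all(zygosity %in% c("het", "hom_alt")))
  ar <- allele_ratio(alt_reads, depth)
  ifelse(zygosity == "het",
         ar >= bounds$het_low & ar <= bounds$het_high,
         ar >= bounds$hom_min)
}

#' Prioritization thresholds
#'
#' The variant-level cascade keeps SNVs only when all three functional
#' predictors call them deleterious (SIFT <= `sift_deleterious_max`,
#' PolyPhen2 >= `polyphen_deleterious_min`, MutationTaster "deleterious"),
#' fewer than two PredictSNP2 component tools call them benign, and the
#' reference-population MAF is strictly below `maf_max_snv`. Indels are kept
#' on the MAF rule alone. A variant seen in more than `recurrence_max`
#' distinct carriers is treated as a platform artifact and removed outright.
#'
#' @param maf_max_snv,maf_max_indel strict MAF upper bounds.
#' @param recurrence_max inclusive maximum number of carrier samples.
#' @param predictsnp2_benign_max inclusive maximum benign-tool count.
#' @param sift_deleterious_max SIFT score at or below which a call is "D".
#' @param polyphen_deleterious_min PolyPhen2 score at or above which a call
#'   is "probably damaging".
#' @param ar_applies_to_indels whether the allele-ratio QC (a read-support
#'   check, not a functional one) is applied to indel calls too.
#' @return object of class `prioritization_criteria`.
#' @export
prioritization_criteria <- function(maf_max_snv = 0.001,
                                    maf_max_indel = 0.001,
                                    recurrence_max = 5L,
                                    predictsnp2_benign_max = 1L,
                                    sift_deleterious_max = 0.05,
                                    polyphen_deleterious_min = 0.909,
                                    ar_applies_to_indels = TRUE) {
  stopifnot(maf_max_snv > 0, maf_max_snv <= 0.5,
            maf_max_indel > 0, maf_max_indel <= 0.5,
            recurrence_max >= 1,
            predictsnp2_benign_max >= 0,
            sift_deleterious_max >= 0, sift_deleterious_max <= 1,
            polyphen_deleterious_min >= 0, polyphen_deleterious_min <= 1)
  structure(list(maf_max_snv = maf_max_snv, maf_max_indel = maf_max_indel,
                 recurrence_max = as.integer(recurrence_max),
                 predictsnp2_benign_max = as.integer(predictsnp2_benign_max),
                 sift_deleterious_max = sift_deleterious_max,
                 polyphen_deleterious_min = polyphen_deleterious_min,
                 ar_applies_to_indels = isTRUE(ar_applies_to_indels)),
            class = "prioritization_criteria")
}

#' Functional-consensus predicate for SNVs
#'
#' TRUE iff all three predictors agree the variant is deleterious, fewer
#' than two PredictSNP2 component tools call it benign, and MAF is strictly
#' below the SNV threshold. A missing required score fails the predicate
#' (conservative: unannotated noise must not flood the gene list); a missing
#' MAF is treated as 0, i.e. absent from reference populations.
#'
#' @param variants variant data.frame (rows from a [cohort_table()]).
#' @param criteria a [prioritization_criteria()].
#' @return logical vector, one element per variant row.
#' @export
passes_functional_consensus <- function(variants,
                                        criteria =
                                          prioritization_criteria()) {
  if (any(variants$variant_class != "SNV"))
    stop("functional consensus applies to SNVs only; ",
         "indels use passes_indel_filter()", call. = FALSE)
  maf <- ifelse(is.na(variants$maf), 0, variants$maf)
  sift_d <- !is.na(variants$sift) &
    variants$sift <= criteria$sift_deleterious_max
  pph_d <- !is.na(variants$polyphen) &
    variants$polyphen >= criteria$polyphen_deleterious_min
  mt_d <- !is.na(variants$mutation_taster) &
    variants$mutation_taster == "deleterious"
  psnp_ok <- !is.na(variants$predictsnp2_benign) &
    variants$predictsnp2_benign <= criteria$predictsnp2_benign_max
  sift_d & pph_d & mt_d & psnp_ok & maf < criteria$maf_max_snv
}

#' Rarity filter for indels
#'
#' Indels lack comparable in-silico deleteriousness scores, so they are kept
#' on rarity alone: MAF strictly below the indel threshold, with missing MAF
#' read as 0.
#'
#' @inheritParams passes_functional_consensus
#' @return logical vector.
#' @export
passes_indel_filter <- function(variants,
                                criteria = prioritization_criteria()) {
  if (any(variants$variant_class == "SNV"))
    stop("indel filter applied to an SNV", call. = FALSE)
  maf <- ifelse(is.na(variants$maf), 0, variants$maf)
  maf < criteria$maf_max_indel
}

#' Remove recurrent (likely artifactual) variants
#'
#' A variant carried by more than `max_samples` distinct case samples (het or
#' hom) is removed entirely, carriers included: in a rare-disease cohort a
#' site recurring that often is more plausibly a platform artifact than a
#' shared causal allele. Counting is over individuals, not alleles.
#'
#' @param cohort a [cohort_table()].
#' @param max_samples inclusive carrier-count ceiling.
#' @return the filtered [cohort_table()].
#' @export
recurrence_filter <- function(cohort, max_samples = 5L) {
  stopifnot(max_samples >= 1)
  g <- cohort$genotypes
  carriers <- tapply(g$sample_id, g$variant_id,
                     function(s) length(unique(s)))
  keep_ids <- names(carriers)[carriers <= max_samples]
  cohort_table(cohort$variants[cohort$variants$variant_id %in%
                                 c(keep_ids, setdiff(cohort$variants$variant_id,
                                                     g$variant_id)), ,
                               drop = FALSE],
               g[g$variant_id %in% keep_ids, , drop = FALSE],
               cohort$samples)
}

#' Run the variant prioritization cascade
#'
#' Applies, in order: the variant-level functional/MAF rules (consensus for
#' SNVs, rarity for indels, MNVs always rejected as un-normalized input),
#' the allele-ratio QC per call, and the recurrence filter on the carriers
#' that survive QC; finally collapses survivors to a deduplicated gene list.
#' The predicates are pure, so the variant-level filters commute; the cascade
#' order only fixes which filter an attrition is attributed to.
#'
#' @param cohort a [cohort_table()].
#' @param criteria a [prioritization_criteria()].
#' @param bounds an [ar_bounds()].
#' @return object of class `prioritized_set`: `pairs` (surviving
#'   variant-by-sample calls with gene, scores and allele ratio),
#'   `genes` (deduplicated symbols), `attrition` (named integer vector over
#'   the cascade, summing with `n_surviving` to the input pair count), and
#'   the thresholds used.
#' @export
prioritize <- function(cohort, criteria = prioritization_criteria(),
                       bounds = ar_bounds()) {
  v <- cohort$variants
  g <- cohort$genotypes
  n_input <- nrow(g)
  attrition <- c(functional = 0L, allele_ratio = 0L, recurrence = 0L)

  if (n_input == 0L) {
    return(structure(list(pairs = cbind(g, allele_ratio = numeric(0)),
                          genes = character(0),
                          attrition = attrition, n_input = 0L,
                          n_surviving = 0L,
                          criteria = criteria, bounds = bounds),
                     class = "prioritized_set"))
  }

  is_snv <- v$variant_class == "SNV"
  is_indel <- v$variant_class == "indel"
  v_pass <- logical(nrow(v))
  v_pass[is_snv] <- passes_functional_consensus(v[is_snv, , drop = FALSE],
                                                criteria)
  v_pass[is_indel] <- passes_indel_filter(v[is_indel, , drop = FALSE],
                                          criteria)
  names(v_pass) <- v$variant_id

  pass1 <- v_pass[g$variant_id]
  attrition["functional"] <- sum(!pass1)
  g1 <- g[pass1, , drop = FALSE]

  ar_ok <- if (nrow(g1)) {
    ok <- passes_allele_ratio(g1$zygosity, g1$alt_reads, g1$depth, bounds)
    if (!criteria$ar_applies_to_indels) {
      indel_ids <- v$variant_id[is_indel]
      ok[g1$variant_id %in% indel_ids] <- TRUE
    }
    ok
  } else logical(0)
  attrition["allele_ratio"] <- sum(!ar_ok)
  g2 <- g1[ar_ok, , drop = FALSE]

  if (nrow(g2)) {
    carriers <- tapply(g2$sample_id, g2$variant_id,
                       function(s) length(unique(s)))
    recurrent <- names(carriers)[carriers > criteria$recurrence_max]
    rec_fail <- g2$variant_id %in% recurrent
  } else rec_fail <- logical(0)
  attrition["recurrence"] <- sum(rec_fail)
  g3 <- g2[!rec_fail, , drop = FALSE]

  vi <- match(g3$variant_id, v$variant_id)
  pairs <- data.frame(g3,
                      gene = v$gene[vi],
                      variant_class = v$variant_class[vi],
                      sift = v$sift[vi], polyphen = v$polyphen[vi],
                      mutation_taster = v$mutation_taster[vi],
                      predictsnp2_benign = v$predictsnp2_benign[vi],
                      maf = v$maf[vi],
                      allele_ratio = if (nrow(g3))
                        allele_ratio(g3$alt_reads, g3$depth) else numeric(0),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  genes <- unique(pairs$gene[!is.na(pairs$gene)])

  structure(list(pairs = pairs, genes = genes, attrition = attrition,
                 n_input = n_input, n_surviving = nrow(pairs),
                 criteria = criteria, bounds = bounds),
            class = "prioritized_set")
}

#' @method print prioritized_set
#' @export
print.prioritized_set <- function(x, ...) {
  cat("Prioritized variant set\n")
  cat("  input calls:     ", x$n_input, "\n")
  cat("  removed:          functional/MAF", x$attrition[["functional"]],
      "| allele ratio", x$attrition[["allele_ratio"]],
      "| recurrence", x$attrition[["recurrence"]], "\n")
  cat("  surviving calls: ", x$n_surviving, "\n")
  cat("  genes:           ", length(x$genes), "\n")
  invisible(x)
}

#' Write prioritization outputs
#'
#' @param x a `prioritized_set`.
#' @param pairs_path TSV of surviving calls; `NULL` to skip.
#' @param genes_path newline-delimited gene list; `NULL` to skip.
#' @param attrition_path TSV attrition ledger; `NULL` to skip.
#' @return `x`, invisibly.
#' @export
write_prioritized <- function(x, pairs_path = NULL, genes_path = NULL,
                              attrition_path = NULL) {
  if (!is.null(pairs_path))
    utils::write.table(x$pairs, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(genes_path))
    writeLines(x$genes, genes_path)
  if (!is.null(attrition_path))
    utils::write.table(
      data.frame(filter = c(names(x$attrition), "surviving"),
                 calls = c(unname(x$attrition), x$n_surviving)),
      attrition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
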