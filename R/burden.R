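#' Qualifying-variant criteria for the burden test
#'
#' The collapsing test counts carriers of "qualifying" variants per gene:
#' SNVs only, carrier-call coverage depth strictly greater than `min_depth`,
#' SIFT at most `sift_max`, PolyPhen2 at least `polyphen_min`, and
#' reference-population MAF strictly below `maf_max`. The depth rule is a
#' property of each carrier call, so a variant may qualify in one sample and
#' not in another.
#'
#' @param snv_only restrict to single-nucleotide variants.
#' @param min_depth exclusive lower bound on carrier-call depth.
#' @param sift_max inclusive SIFT ceiling.
#' @param polyphen_min inclusive PolyPhen2 floor.
#' @param maf_max exclusive MAF ceiling.
#' @return object of class `qualifying_criteria`.
#' @export
qualifying_criteria <- function(snv_only = TRUE, min_depth = 10L,
                                sift_max = 0.05, polyphen_min = 0.8,
                                maf_max = 0.01) {
  stopifnot(min_depth >= 0, sift_max >= 0, sift_max <= 1,
            polyphen_min >= 0, polyphen_min <= 1,
            maf_max > 0, maf_max <= 0.5)
  structure(list(snv_only = isTRUE(snv_only),
                 min_depth = as.integer(min_depth),
                 sift_max = sift_max, polyphen_min = polyphen_min,
                 maf_max = maf_max),
            class = "qualifying_criteria")
}

#' Select qualifying calls per gene (the "SNP file")
#'
#' Applies the [qualifying_criteria()] to every non-reference call of the
#' cohort. Variant-level rules (class, SIFT, PolyPhen2, MAF) are combined
#' with the per-call depth rule; missing required scores disqualify the
#' variant. Missing MAF is treated as 0.
#'
#' @param cohort a [cohort_table()].
#' @param criteria a [qualifying_criteria()].
#' @return data.frame of qualifying calls with gene annotation: variant_id,
#'   sample_id, zygosity, alt_reads, depth, gene.
#' @export
select_qualifying <- function(cohort, criteria = qualifying_criteria()) {
  v <- cohort$variants
  g <- cohort$genotypes
  if (nrow(g) == 0L)
    return(cbind(empty_genotypes(), gene = character(0)))
  maf <- ifelse(is.na(v$maf), 0, v$maf)
  v_ok <- (!criteria$snv_only | v$variant_class == "SNV") &
    !is.na(v$sift) & v$sift <= criteria$sift_max &
    !is.na(v$polyphen) & v$polyphen >= criteria$polyphen_min &
    maf < criteria$maf_max & !is.na(v$gene)
  names(v_ok) <- v$variant_id
  keep <- v_ok[g$variant_id] & g$depth > criteria$min_depth
  out <- g[keep, , drop = FALSE]
  out$gene <- v$gene[match(out$variant_id, v$variant_id)]
  rownames(out) <- NULL
  out
}

#' Count case carriers of a gene under both inheritance models
#'
#' Each sample with any qualifying call in the gene is classified once:
#' `hom` if it carries any homozygous-alt qualifying call; otherwise `ch`
#' (putative compound heterozygote, phase unknown) if it carries qualifying
#' het calls at two or more distinct sites; otherwise `het`. Dominant
#' carriers are het + hom; recessive carriers are ch + hom. `het_carriers`
#' includes the ch samples (a compound het is in particular a het carrier).
#'
#' @param gene_calls qualifying calls of one gene
#'   (rows of [select_qualifying()] output).
#' @param n_cases number of samples on the cohort roster.
#' @return list: gene counts `het_carriers`, `hom_carriers`, `ch_carriers`,
#'   `dom_carriers`, `rec_carriers`, `total_ac`.
#' @export
count_case_models <- function(gene_calls, n_cases) {
  if (nrow(gene_calls) == 0L)
    return(list(het_carriers = 0L, hom_carriers = 0L, ch_carriers = 0L,
                dom_carriers = 0L, rec_carriers = 0L, total_ac = 0L))
  by_sample <- split(gene_calls, gene_calls$sample_id)
  has_hom <- vapply(by_sample, function(d) any(d$zygosity == "hom_alt"),
                    logical(1))
  n_het_sites <- vapply(by_sample, function(d)
    length(unique(d$variant_id[d$zygosity == "het"])), integer(1))
  hom_carriers <- sum(has_hom)
  het_carriers <- sum(!has_hom & n_het_sites >= 1L)
  ch_carriers <- sum(!has_hom & n_het_sites >= 2L)
  dom <- het_carriers + hom_carriers
  if (dom > n_cases)
    stop("carrier count exceeds cohort size", call. = FALSE)
  list(het_carriers = het_carriers, hom_carriers = hom_carriers,
       ch_carriers = ch_carriers,
       dom_carriers = dom, rec_carriers = ch_carriers + hom_carriers,
       total_ac = sum(ifelse(gene_calls$zygosity == "het", 1L, 2L)))
}

#' Aggregate control summary statistics for one gene
#'
#' Two constructions, reflecting how much the control summary says about
#' gene membership. When the summary carries a `gene` column (a control-side
#' "SNP file": every qualifying site of the gene in the control population),
#' control AC/nhom are summed over all of the gene's control sites passing
#' the control-side qualifying rules — the construction behind published
#' burden tables, where a gene's control AC spans every rare deleterious
#' site in the gene, not just the handful the cases happened to carry.
#' Without gene assignments the sums fall back to the case-qualifying sites
#' only; this fallback conditions the control margin on case carriers and is
#' anti-conservative for sparsely hit genes, so a gene-annotated summary is
#' preferred whenever available.
#'
#' @param variant_ids qualifying case variant ids of the gene.
#' @param control_summary data.frame from [read_control_summary()],
#'   optionally with `gene` and precomputed `qualifying` columns.
#' @param gene gene symbol, used when the summary carries assignments.
#' @return list: `control_ac_sum`, `control_nhom_sum`, `control_freqs`
#'   (per-site allele frequencies entering the recessive estimate),
#'   `n_missing` (case sites absent from the summary; they contribute 0).
#' @export
gene_control_counts <- function(variant_ids, control_summary,
                                gene = NULL) {
  variant_ids <- unique(variant_ids)
  miss <- !(variant_ids %in% control_summary$variant_id)
  if (!is.null(gene) && !is.null(control_summary$gene)) {
    rows <- control_summary[control_summary$gene %in% gene &
                              control_summary$qualifying, , drop = FALSE]
  } else {
    rows <- control_summary[match(variant_ids[!miss],
                                  control_summary$variant_id), ,
                            drop = FALSE]
  }
  list(control_ac_sum = sum(rows$control_ac),
       control_nhom_sum = sum(rows$control_nhom),
       control_freqs = if (nrow(rows)) rows$control_ac / rows$control_an
                       else 0,
       n_missing = sum(miss))
}

# Control-side qualifying flag: SNV with control frequency under the MAF
# ceiling; functional scores are checked when the site is also present in
# the case variant table (control-only sites carry no annotations here).
control_qualifying <- function(control_summary, variants, criteria) {
  q <- nchar(control_summary$ref) == 1L &
    nchar(control_summary$alt) == 1L &
    control_summary$control_ac / control_summary$control_an <
      criteria$maf_max
  vi <- match(control_summary$variant_id, variants$variant_id)
  known <- !is.na(vi)
  q[known] <- q[known] &
    !is.na(variants$sift[vi[known]]) &
    variants$sift[vi[known]] <= criteria$sift_max &
    !is.na(variants$polyphen[vi[known]]) &
    variants$polyphen[vi[known]] >= criteria$polyphen_min
  q
}

#' Dominant-model contingency table
#'
#' Case side: individuals carrying at least one qualifying allele vs not.
#' Control side: the summed control allele count stands in for carrier
#' individuals, each allele assumed to sit in a distinct person and capped
#' at the control cohort size. With rare variants the approximation error is
#' negligible and it errs conservative (it can only overstate control
#' carriers).
#'
#' @param dom_carriers case dominant carriers (het + hom individuals).
#' @param control_ac_sum summed control allele count over the gene's
#'   qualifying variants.
#' @param n_cases case cohort size.
#' @param control_n control cohort size (individuals).
#' @return 2x2 integer matrix `[cases; controls] x [carrier; non-carrier]`.
#' @export
dominant_contingency <- function(dom_carriers, control_ac_sum, n_cases,
                                 control_n) {
  if (dom_carriers > n_cases)
    stop("dominant carriers exceed n_cases", call. = FALSE)
  cc <- min(control_ac_sum, control_n)
  matrix(c(dom_carriers, n_cases - dom_carriers, cc, control_n - cc),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"),
                         c("carrier", "non_carrier")))
}

#' Recessive-model contingency table
#'
#' Case side: individuals with a putative biallelic genotype (compound het
#' or hom). The control side cannot be observed from summary statistics, so
#' two constructions are offered: `reported_hom` uses the summed control
#' homozygote count (ignores control compound hets, anti-conservative);
#' `expected_biallelic` estimates biallelic control carriers under
#' independence of sites as `round(control_n * (1 - prod(1 - f_i))^2)` with
#' f_i the per-site control allele frequencies, which treats the two
#' haplotypes of an individual as independent draws.
#'
#' @param rec_carriers case recessive carriers (ch + hom individuals).
#' @param ctrl list from [gene_control_counts()].
#' @param n_cases case cohort size.
#' @param control_n control cohort size.
#' @param strategy `"reported_hom"` or `"expected_biallelic"`.
#' @return 2x2 integer matrix as in [dominant_contingency()].
#' @export
recessive_contingency <- function(rec_carriers, ctrl, n_cases, control_n,
                                  strategy = c("reported_hom",
                                               "expected_biallelic")) {
  strategy <- match.arg(strategy)
  if (rec_carriers > n_cases)
    stop("recessive carriers exceed n_cases", call. = FALSE)
  cc <- switch(strategy,
               reported_hom = ctrl$control_nhom_sum,
               expected_biallelic = {
                 q <- 1 - prod(1 - ctrl$control_freqs)
                 round(control_n * q^2)
               })
  cc <- min(cc, control_n)
  matrix(c(rec_carriers, n_cases - rec_carriers, cc, control_n - cc),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"),
                         c("carrier", "non_carrier")))
}

#' One-sided Fisher exact test (excess in cases)
#'
#' Upper-tail hypergeometric probability P(X >= a) of the top-left cell
#' conditioning on the table margins — the exact one-sided test of carrier
#' excess in cases. An all-zero table has nothing to test and returns 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts, cases in row 1,
#'   carriers in column 1.
#' @return the one-sided p-value.
#' @export
fisher_one_sided_greater <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]
  if (sum(tab) == 0) return(1)
  # margins: carriers m = a+c, non-carriers n = b+d, cases drawn k = a+b
  stats::phyper(a - 1, m = a + tab[2, 1], n = tab[1, 2] + tab[2, 2],
                k = a + tab[1, 2], lower.tail = FALSE)
}

#' Per-gene collapsing burden scan against summary controls
#'
#' For every gene with at least one qualifying case call (optionally
#' restricted to `gene_subset`), counts case carriers under the dominant and
#' recessive models, builds the matching control-side tables from the
#' summary statistics, tests each with the one-sided Fisher exact test
#' (excess in cases), and adjusts per model with Benjamini-Hochberg across
#' the genes tested. Genes without qualifying case variants are excluded
#' from testing and from the adjustment family m.
#'
#' @param cohort a [cohort_table()].
#' @param control_summary data.frame from [read_control_summary()]; a
#'   gene-annotated summary enables control-side per-gene sums (preferred,
#'   see [gene_control_counts()]).
#' @param control_n control cohort size in individuals.
#' @param gene_subset optional character vector restricting the tested genes
#'   (e.g. the genes of a significant enrichment term).
#' @param criteria a [qualifying_criteria()].
#' @param recessive_strategy control construction for the recessive model,
#'   see [recessive_contingency()].
#' @param alternative `"greater"` (one-sided excess in cases, default) or
#'   `"two.sided"`.
#' @param alpha FDR significance threshold.
#' @return data.frame of class `burden_scan`, one row per tested gene,
#'   sorted by dominant p: gene, case het/hom/ch carrier counts, case total
#'   AC, control AC and nhom sums, p and FDR under both models,
#'   significance flags. Attributes: `n_cases`, `control_n`, `m` (family
#'   size), `missing_control_sites`.
#' @export
run_burden_scan <- function(cohort, control_summary,
                            control_n = 125748L,
                            gene_subset = NULL,
                            criteria = qualifying_criteria(),
                            recessive_strategy = "reported_hom",
                            alternative = c("greater", "two.sided"),
                            alpha = 0.05) {
  alternative <- match.arg(alternative)
  ncase <- n_cases(cohort)
  qual <- select_qualifying(cohort, criteria)
  if (!is.null(gene_subset))
    qual <- qual[qual$gene %in% gene_subset, , drop = FALSE]
  genes <- sort(unique(qual$gene))
  miss_total <- 0L
  if (!is.null(control_summary$gene))
    control_summary$qualifying <-
      control_qualifying(control_summary, cohort$variants, criteria)

  rows <- lapply(genes, function(gn) {
    calls <- qual[qual$gene == gn, , drop = FALSE]
    cc <- count_case_models(calls, ncase)
    ctrl <- gene_control_counts(calls$variant_id, control_summary, gn)
    miss_total <<- miss_total + ctrl$n_missing
    dom_tab <- dominant_contingency(cc$dom_carriers, ctrl$control_ac_sum,
                                    ncase, control_n)
    rec_tab <- recessive_contingency(cc$rec_carriers, ctrl, ncase,
                                     control_n, recessive_strategy)
    p_dom <- if (alternative == "greater") fisher_one_sided_greater(dom_tab)
             else stats::fisher.test(dom_tab)$p.value
    p_rec <- if (alternative == "greater") fisher_one_sided_greater(rec_tab)
             else stats::fisher.test(rec_tab)$p.value
    data.frame(gene = gn,
               case_het = cc$het_carriers, case_hom = cc$hom_carriers,
               case_ch = cc$ch_carriers, case_ac = cc$total_ac,
               dom_carriers = cc$dom_carriers,
               rec_carriers = cc$rec_carriers,
               control_ac = ctrl$control_ac_sum,
               control_nhom = ctrl$control_nhom_sum,
               p_dom = p_dom, p_rec = p_rec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), case_het = integer(),
                      case_hom = integer(), case_ch = integer(),
                      case_ac = integer(), dom_carriers = integer(),
                      rec_carriers = integer(), control_ac = integer(),
                      control_nhom = integer(),
                      p_dom = numeric(), p_rec = numeric())
  m <- nrow(out)
  out$fdr_dom <- if (m) bh_adjust(out$p_dom) else numeric(0)
  out$fdr_rec <- if (m) bh_adjust(out$p_rec) else numeric(0)
  out$sig_dom <- out$fdr_dom < alpha
  out$sig_rec <- out$fdr_rec < alpha
  out <- out[order(out$p_dom, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("burden_scan", "data.frame"),
            n_cases = ncase, control_n = control_n, m = m,
            alpha = alpha, recessive_strategy = recessive_strategy,
            missing_control_sites = miss_total)
}

#' @method print burden_scan
#' @export
print.burden_scan <- function(x, n = 10L, ...) {
  cat("Burden scan:", nrow(x), "genes tested |", attr(x, "n_cases"),
      "cases vs", attr(x, "control_n"), "summary controls\n")
  cat("  significant at FDR <", attr(x, "alpha"), ":",
      sum(x$sig_dom), "dominant,", sum(x$sig_rec), "recessive",
      paste0("(", attr(x, "recessive_strategy"), ")"), "\n")
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("gene", "case_het", "case_hom", "case_ch",
                           "case_ac", "control_ac", "p_dom", "fdr_dom",
                           "p_rec", "fdr_rec")]
  for (cl in c("p_dom", "fdr_dom", "p_rec", "fdr_rec"))
    df[[cl]] <- signif(df[[cl]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @method summary burden_scan
#' @export
summary.burden_scan <- function(object, ...) {
  cat("Genes tested (family size m):", attr(object, "m"), "\n")
  cat("Dominant significant:", sum(object$sig_dom),
      "| recessive significant:", sum(object$sig_rec),
      "| union:", sum(object$sig_dom | object$sig_rec), "\n")
  cat("Qualifying sites absent from control summary:",
      attr(object, "missing_control_sites"), "\n")
  im <- implied_m(object$p_dom, object$fdr_dom)
  if (!is.na(im))
    cat("Implied BH family size from dominant p/FDR pairs:",
        round(im, 1), "\n")
  invisible(object)
}

#' Implied Benjamini-Hochberg family size
#'
#' For BH-adjusted values without step-up ties, fdr_i * rank_i / p_i equals
#' the family size m; the median over rows recovers the m actually used.
#' Useful as a diagnostic when comparing against published tables whose
#' adjustment family is unstated.
#'
#' @param p raw p-values.
#' @param fdr matching BH-adjusted values.
#' @return the median implied m (NA if no usable rows).
#' @export
implied_m <- function(p, fdr) {
  ok <- !is.na(p) & !is.na(fdr) & p > 0 & fdr < 1
  if (!any(ok)) return(NA_real_)
  r <- rank(p, ties.method = "first")
  stats::median(fdr[ok] * r[ok] / p[ok])
}
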