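#' Default annotation field map for cohort VCFs
#'
#' Names the INFO and FORMAT keys that carry the per-variant annotations and
#' per-sample read support the pipeline consumes. Annotation engines differ in
#' how they encode these, so every key is remappable; the defaults match the
#' plain INFO-key layout written by [write_cohort_vcf()].
#'
#' @param gene INFO key holding the gene symbol (mandatory in the input).
#' @param sift,polyphen INFO keys for SIFT and PolyPhen2 scores in \[0, 1\].
#' @param mutation_taster INFO key for the MutationTaster class
#'   (`"deleterious"` or `"benign"`).
#' @param predictsnp2_benign INFO key for the count of PredictSNP2 component
#'   tools calling the variant benign/tolerated.
#' @param maf INFO key for the reference-population minor allele frequency.
#' @param ad FORMAT key for per-sample allelic depths (`ref,alt`).
#' @param dp FORMAT key for per-sample total depth.
#' @return A named list of key names.
#' @export
annotation_field_map <- function(gene = "GENE", sift = "SIFT",
                                 polyphen = "PPH2",
                                 mutation_taster = "MT",
                                 predictsnp2_benign = "PSNP2B",
                                 maf = "MAF", ad = "AD", dp = "DP") {
  list(gene = gene, sift = sift, polyphen = polyphen,
       mutation_taster = mutation_taster,
       predictsnp2_benign = predictsnp2_benign, maf = maf, ad = ad, dp = dp)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

classify_variant <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV", ifelse(lr == la, "MNV", "indel"))
}

#' Assemble a case-cohort table
#'
#' The in-memory representation used by every downstream stage: a variant
#' table, a long genotype table holding one row per non-reference call, and
#' the sample roster (so samples with no surviving calls still count towards
#' `n_cases`). Variant identity is the tuple (chrom, pos, ref, alt); records
#' must be normalized and biallelic before entry.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `sift`, `polyphen`, `mutation_taster`, `predictsnp2_benign`,
#'   `maf`. A `variant_id` column and `variant_class` are derived if absent.
#'   Missing MAF is coerced to 0 (absent from reference populations).
#' @param genotypes data.frame with columns `variant_id`, `sample_id`,
#'   `zygosity` (`"het"` or `"hom_alt"`), `alt_reads`, `depth`.
#' @param samples character vector of case sample ids.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(variants, genotypes, samples) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (nrow(variants)) {
    if (is.null(variants$variant_id))
      variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                         variants$ref, variants$alt)
    if (is.null(variants$variant_class))
      variants$variant_class <- classify_variant(variants$ref, variants$alt)
    variants$maf[is.na(variants$maf)] <- 0
  }
  obj <- structure(list(variants = variants, genotypes = genotypes,
                        samples = as.character(samples)),
                   class = "cohort_table")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  v <- x$variants
  g <- x$genotypes
  if (nrow(v)) {
    if (any(grepl(",", v$alt, fixed = TRUE)))
      stop("multiallelic ALT found; pre-split records into biallelic form ",
           "(e.g. bcftools norm -m -) before loading", call. = FALSE)
    if (any(v$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
    if (any(v$ref == v$alt)) stop("ref and alt alleles must differ",
                                  call. = FALSE)
    if (anyDuplicated(v$variant_id))
      stop("duplicate variant records: ",
           paste(unique(v$variant_id[duplicated(v$variant_id)]),
                 collapse = ", "), call. = FALSE)
    cls <- classify_variant(v$ref, v$alt)
    if (any(v$variant_class != cls))
      stop("variant_class inconsistent with ref/alt lengths", call. = FALSE)
  }
  if (nrow(g)) {
    if (!all(g$variant_id %in% v$variant_id))
      stop("genotype references unknown variant", call. = FALSE)
    if (!all(g$sample_id %in% x$samples))
      stop("genotype references sample not on the roster", call. = FALSE)
    if (!all(g$zygosity %in% c("het", "hom_alt")))
      stop("zygosity must be 'het' or 'hom_alt'", call. = FALSE)
    if (any(g$alt_reads > g$depth))
      stop("alt_reads exceeds depth", call. = FALSE)
    if (any(g$depth < 1)) stop("depth must be positive", call. = FALSE)
  }
  invisible(x)
}

#' @method print cohort_table
#' @export
print.cohort_table <- function(x, ...) {
  cat("Case cohort:", length(x$samples), "samples,",
      nrow(x$variants), "variants,", nrow(x$genotypes),
      "non-reference calls\n")
  tab <- table(x$variants$variant_class)
  if (length(tab))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

n_cases <- function(cohort) length(cohort$samples)

info_field <- function(vcf, key, numeric = FALSE) {
  out <- suppressWarnings(
    vcfR::extract.info(vcf, element = key, as.numeric = numeric))
  out
}

#' Read an annotated multi-sample cohort VCF
#'
#' Expects a normalized, biallelic VCF (one ALT per record) with per-variant
#' annotations in INFO and per-sample `GT`, allelic depths and depth in
#' FORMAT, under the keys named by `field_map`. Reference and no-call
#' genotypes are not stored. Calls violating read-support invariants
#' (alt reads > depth, depth < 1) are dropped and counted in the
#' `"rejected_calls"` attribute.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param field_map key mapping from [annotation_field_map()].
#' @return A [cohort_table()]; attribute `rejected_calls` counts dropped
#'   calls.
#' @export
read_cohort_vcf <- function(path, field_map = annotation_field_map()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(cohort_table(empty_variants(), empty_genotypes(),
                        colnames(vcf@gt)[-1]))
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic record at ",
         fix$CHROM[grepl(",", fix$ALT)][1], ":",
         fix$POS[grepl(",", fix$ALT)][1],
         "; pre-split into biallelic records (bcftools norm -m -)",
         call. = FALSE)

  meta_ids <- vcfR::queryMETA(vcf)
  has_key <- function(key) any(grepl(paste0("ID=", key, "($|,)"), meta_ids))
  if (!has_key(field_map$gene))
    stop("annotation key '", field_map$gene,
         "' not declared in the VCF header; set annotation_field_map()",
         call. = FALSE)

  gene <- info_field(vcf, field_map$gene)
  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = gene,
    sift = info_field(vcf, field_map$sift, numeric = TRUE),
    polyphen = info_field(vcf, field_map$polyphen, numeric = TRUE),
    mutation_taster = info_field(vcf, field_map$mutation_taster),
    predictsnp2_benign = suppressWarnings(
      as.integer(info_field(vcf, field_map$predictsnp2_benign))),
    maf = info_field(vcf, field_map$maf, numeric = TRUE),
    stringsAsFactors = FALSE)
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = field_map$ad)
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = field_map$dp, as.numeric = TRUE))
  samples <- colnames(gt)
  rownames(gt) <- variants$variant_id

  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  is_het <- matrix(gt_clean %in% c("0/1", "1/0"), nrow = nrow(gt))
  is_hom <- matrix(gt_clean %in% "1/1", nrow = nrow(gt))
  idx <- which(is_het | is_hom, arr.ind = TRUE)
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(ad[idx], ",", fixed = TRUE),
                      function(z) if (length(z) >= 2) z[2] else NA_character_,
                      character(1))))
  genotypes <- data.frame(
    variant_id = variants$variant_id[idx[, 1]],
    sample_id = samples[idx[, 2]],
    zygosity = ifelse(is_het[idx], "het", "hom_alt"),
    alt_reads = alt_reads,
    depth = as.integer(dp[idx]),
    stringsAsFactors = FALSE)

  bad <- is.na(genotypes$alt_reads) | is.na(genotypes$depth) |
    genotypes$depth < 1 | genotypes$alt_reads > genotypes$depth
  rejected <- sum(bad)
  genotypes <- genotypes[!bad, , drop = FALSE]
  rownames(genotypes) <- NULL

  out <- cohort_table(variants, genotypes, samples)
  attr(out, "rejected_calls") <- rejected
  out
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), sift = numeric(),
             polyphen = numeric(), mutation_taster = character(),
             predictsnp2_benign = integer(), maf = numeric(),
             variant_id = character(), variant_class = character(),
             stringsAsFactors = FALSE)
}

empty_genotypes <- function() {
  data.frame(variant_id = character(), sample_id = character(),
             zygosity = character(), alt_reads = integer(),
             depth = integer(), stringsAsFactors = FALSE)
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.17g", x))
}

#' Write a cohort table as a multi-sample VCF
#'
#' Emits an uncompressed VCF v4.2 with the package's plain INFO keys (see
#' [annotation_field_map()]) and `GT:AD:DP` genotypes. Numeric annotations
#' are printed with full double precision so a write/read cycle through
#' [read_cohort_vcf()] is lossless.
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  g <- cohort$genotypes
  samples <- cohort$samples
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=PPH2,Number=1,Type=Float,Description=\"PolyPhen2 score\">",
    "##INFO=<ID=MT,Number=1,Type=String,Description=\"MutationTaster class\">",
    paste0("##INFO=<ID=PSNP2B,Number=1,Type=Integer,Description=",
           "\"PredictSNP2 component tools calling benign/tolerated\">"),
    paste0("##INFO=<ID=MAF,Number=1,Type=Float,Description=",
           "\"Reference population minor allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (nrow(v) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  info <- paste0("GENE=", ifelse(is.na(v$gene), ".", v$gene),
                 ";SIFT=", fmt_num(v$sift),
                 ";PPH2=", fmt_num(v$polyphen),
                 ";MT=", ifelse(is.na(v$mutation_taster), ".",
                                v$mutation_taster),
                 ";PSNP2B=", ifelse(is.na(v$predictsnp2_benign), ".",
                                    v$predictsnp2_benign),
                 ";MAF=", fmt_num(v$maf))
  gtmat <- matrix("0/0:.:.", nrow = nrow(v), ncol = length(samples),
                  dimnames = list(v$variant_id, samples))
  if (nrow(g)) {
    gtfield <- paste0(ifelse(g$zygosity == "het", "0/1", "1/1"), ":",
                      g$depth - g$alt_reads, ",", g$alt_reads, ":", g$depth)
    gtmat[cbind(match(g$variant_id, v$variant_id),
                match(g$sample_id, samples))] <- gtfield
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT:AD:DP",
                apply(gtmat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population-control site summary
#'
#' Accepts either a tab-separated table with header
#' `chrom pos ref alt ac an nhom` or a sites-only VCF carrying INFO fields
#' `AC`, `AN` and `nhomalt` (gnomAD convention). The TSV form may carry an
#' optional eighth column `gene` assigning each site to a gene; a
#' gene-annotated summary lets the burden test sum control counts over all
#' of a gene's qualifying sites (a control-side SNP file) instead of only
#' the sites cases happened to carry. Sites absent from the file are simply
#' absent from the map; downstream their contribution is zero.
#'
#' @param path path to the summary table or sites VCF.
#' @return data.frame with `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `control_ac`, `control_an`, `control_nhom`.
#' @export
read_control_summary <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "##fileformat")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    out <- data.frame(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      control_ac = as.integer(info_field(vcf, "AC")),
      control_an = as.integer(info_field(vcf, "AN")),
      control_nhom = as.integer(info_field(vcf, "nhomalt")),
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (nrow(out)) {
      names(out)[1:7] <- c("chrom", "pos", "ref", "alt",
                           "control_ac", "control_an", "control_nhom")
      for (cl in c("pos", "control_ac", "control_an", "control_nhom"))
        out[[cl]] <- as.integer(out[[cl]])
    } else {
      out <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        control_ac = integer(), control_an = integer(),
                        control_nhom = integer(), stringsAsFactors = FALSE)
    }
  }
  if (nrow(out)) {
    if (any(out$control_ac > out$control_an))
      stop("control summary invalid: AC > AN at ",
           with(out[out$control_ac > out$control_an, ][1, ],
                paste0(chrom, ":", pos)), call. = FALSE)
    if (any(2L * out$control_nhom > out$control_ac))
      stop("control summary invalid: 2*nhom > AC", call. = FALSE)
    out$variant_id <- variant_key(out$chrom, out$pos, out$ref, out$alt)
    if (anyDuplicated(out$variant_id))
      stop("duplicate control summary rows", call. = FALSE)
  } else {
    out$variant_id <- character()
  }
  out
}

#' Write a control summary table
#' @param summary data.frame as returned by [read_control_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_control_summary <- function(summary, path) {
  cols <- c("chrom", "pos", "ref", "alt",
            "control_ac", "control_an", "control_nhom")
  out <- summary[, cols]
  names(out) <- c("chrom", "pos", "ref", "alt", "ac", "an", "nhom")
  if (!is.null(summary$gene)) out$gene <- summary$gene
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `term_id <TAB> description <TAB> gene...`. Genes absent from
#' the background universe are dropped from each term and counted in the
#' `"dropped_genes"` attribute; the background is always explicit because
#' overrepresentation p-values are meaningless without it.
#'
#' @param path path to a GMT file.
#' @param background character vector: the gene universe.
#' @return A `gene_set_collection`: list with `terms` (named list of
#'   `list(name, genes)`) and `background`.
#' @export
read_gene_sets <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set term id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  dropped <- 0L
  terms <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    keep <- genes %in% background
    dropped <<- dropped + sum(!keep)
    list(name = if (length(p) >= 2) p[2] else "", genes = genes[keep])
  })
  names(terms) <- ids
  out <- gene_set_collection(terms, background)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Construct a validated gene-set collection
#' @param terms named list; each element `list(name =, genes =)`.
#' @param background character vector containing every term gene.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, background) {
  background <- unique(as.character(background))
  for (id in names(terms)) {
    if (!all(terms[[id]]$genes %in% background))
      stop("term ", id, " contains genes outside the background",
           call. = FALSE)
  }
  structure(list(terms = terms, background = background),
            class = "gene_set_collection")
}

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$genes), integer(1))
  cat("Gene-set collection:", length(x$terms), "terms over",
      length(x$background), "background genes\n")
  if (length(sizes))
    cat("  term sizes:", min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
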