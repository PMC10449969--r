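#' Specification for a synthetic case cohort
#'
#' Describes the generative model behind [simulate_cohort()] and
#' [simulate_control_summary()]: a catalogue of genes, each with a fixed
#' number of SNV sites segregating at a per-site control allele frequency;
#' case carrier probability per site is the control carrier probability
#' times a per-gene enrichment multiplier (1 = null gene). Artifact calls
#' get an allelic balance outside the het QC band; recurrent-artifact sites
#' are planted in more than `recurrence_max` samples and are absent from the
#' control summary (novel artifacts). Defaults mirror a 50-case exome cohort
#' screened against a 125,748-individual population summary.
#'
#' @param n_cases number of case samples.
#' @param n_genes genes in the catalogue.
#' @param sites_per_gene variant sites per gene.
#' @param control_f per-site control alternate-allele frequency (scalar or
#'   per-gene vector).
#' @param multiplier per-gene case enrichment multiplier (scalar or vector
#'   of length `n_genes`); 1 means cases draw at control frequency.
#' @param recessive_spike logical per gene: also plant biallelic (compound
#'   het) case carriers at rate `multiplier * q^2`, q the gene's control
#'   carrier haplotype frequency.
#' @param artifact_fraction proportion of emitted calls whose allelic
#'   balance is drawn outside the het QC band.
#' @param n_recurrent_sites number of artifact sites planted in more than
#'   `recurrence_max` samples.
#' @param recurrence_max the carrier ceiling those sites must exceed.
#' @param p_damaging probability a site's annotations pass all functional
#'   score filters (SIFT, PolyPhen2, MutationTaster, PredictSNP2).
#' @param indel_fraction proportion of catalogue sites emitted as indels
#'   (no functional scores, rarity-filtered only).
#' @param low_depth_fraction proportion of calls with depth <= 10,
#'   exercising the burden test's depth rule.
#' @param control_n control cohort size in individuals.
#' @param seed mandatory RNG seed; all generator output is a deterministic
#'   function of the spec.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_cases = 50L, n_genes = 200L,
                            sites_per_gene = 10L, control_f = 5e-4,
                            multiplier = 1, recessive_spike = FALSE,
                            artifact_fraction = 0,
                            n_recurrent_sites = 0L, recurrence_max = 5L,
                            p_damaging = 1, indel_fraction = 0,
                            low_depth_fraction = 0,
                            control_n = 125748L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  multiplier <- rep_len(multiplier, n_genes)
  control_f <- rep_len(control_f, n_genes)
  recessive_spike <- rep_len(recessive_spike, n_genes)
  stopifnot(all(control_f >= 0), all(control_f <= 0.5),
            all(multiplier >= 1),
            artifact_fraction >= 0, artifact_fraction <= 1,
            p_damaging >= 0, p_damaging <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            low_depth_fraction >= 0, low_depth_fraction <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_genes = as.integer(n_genes),
                 sites_per_gene = as.integer(sites_per_gene),
                 control_f = control_f, multiplier = multiplier,
                 recessive_spike = recessive_spike,
                 artifact_fraction = artifact_fraction,
                 n_recurrent_sites = as.integer(n_recurrent_sites),
                 recurrence_max = as.integer(recurrence_max),
                 p_damaging = p_damaging,
                 indel_fraction = indel_fraction,
                 low_depth_fraction = low_depth_fraction,
                 control_n = as.integer(control_n),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# Deterministic site layout shared by the cohort and control generators:
# gene g contributes sites_per_gene sites on chromosome "1" at
# (g-1)*10000 + 100*site. No RNG here, so the control summary matches the
# cohort's variant grid regardless of sampling order.
sim_site_grid <- function(spec) {
  g_idx <- rep(seq_len(spec$n_genes), each = spec$sites_per_gene)
  s_idx <- rep(seq_len(spec$sites_per_gene), times = spec$n_genes)
  data.frame(
    gene = sprintf("G%04d", g_idx),
    gene_idx = g_idx,
    chrom = "1",
    pos = (g_idx - 1L) * 10000L + 100L * s_idx,
    f = spec$control_f[g_idx],
    multiplier = spec$multiplier[g_idx],
    stringsAsFactors = FALSE)
}

# Clean het calls get AR in [0.40, 0.60], clean hom in [0.95, 1]; for every
# depth >= 7 the rounded alt count keeps AR inside the inclusive QC band.
# Artifact ranges are chosen so the realized ratio always falls outside it.
sim_alt_reads <- function(zygosity, depth, artifact) {
  n <- length(depth)
  alt <- numeric(n)
  het <- zygosity == "het"
  cl_het <- het & !artifact
  alt[cl_het] <- round(stats::runif(sum(cl_het), 0.40, 0.60) *
                         depth[cl_het])
  cl_hom <- !het & !artifact
  alt[cl_hom] <- round(stats::runif(sum(cl_hom), 0.95, 1.00) *
                         depth[cl_hom])
  side_hi <- stats::runif(n) < 0.5
  hi <- het & artifact & side_hi
  lo <- het & artifact & !side_hi
  alt[hi] <- round(stats::runif(sum(hi), 0.72, 0.85) * depth[hi])
  alt[lo] <- floor(stats::runif(sum(lo), 0.05, 0.30) * depth[lo])
  a_hom <- !het & artifact
  alt[a_hom] <- floor(stats::runif(sum(a_hom), 0.40, 0.80) * depth[a_hom])
  as.integer(pmin(pmax(alt, 0), depth))
}

#' Simulate an annotated case cohort with ground-truth labels
#'
#' Draws genotypes, read support and annotations per the generative model of
#' [cohort_sim_spec()], and returns both the cohort and the bookkeeping the
#' generator used, so every downstream filter can be checked against what
#' was actually planted rather than against intent.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `cohort` (a [cohort_table()]) and `truth`:
#'   `variants` (damaging flag, recurrent-artifact flag, per-variant
#'   prioritization survival), `pairs` (per-call artifact flag and
#'   call-level survival of the prioritization cascade), `genes`
#'   (multiplier, spike model).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  grid <- sim_site_grid(spec)
  ns <- nrow(grid)

  is_indel <- stats::runif(ns) < spec$indel_fraction
  damaging <- stats::runif(ns) < spec$p_damaging
  sift <- ifelse(damaging, stats::runif(ns, 0, 0.05),
                 stats::runif(ns, 0.06, 1))
  polyphen <- ifelse(damaging, stats::runif(ns, 0.91, 0.999),
                     stats::runif(ns, 0, 0.79))
  mt <- ifelse(damaging, "deleterious", "benign")
  psnp <- ifelse(damaging, sample(0:1, ns, replace = TRUE),
                 sample(2:5, ns, replace = TRUE))
  variants <- data.frame(
    chrom = grid$chrom, pos = grid$pos,
    ref = "A", alt = ifelse(is_indel, "AT", "G"),
    gene = grid$gene,
    sift = ifelse(is_indel, NA_real_, sift),
    polyphen = ifelse(is_indel, NA_real_, polyphen),
    mutation_taster = ifelse(is_indel, NA_character_, mt),
    predictsnp2_benign = ifelse(is_indel, NA_integer_, psnp),
    maf = grid$f, stringsAsFactors = FALSE)
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)

  samples <- sprintf("case%03d", seq_len(spec$n_cases))

  # per-site carrier draws
  p_ctrl <- 1 - (1 - grid$f)^2
  p_case <- pmin(1, grid$multiplier * p_ctrl)
  p_hom_given_carrier <- ifelse(p_ctrl > 0, grid$f^2 / p_ctrl, 0)
  carrier <- matrix(stats::runif(ns * spec$n_cases), nrow = ns) <
    p_case
  idx <- which(carrier, arr.ind = TRUE)
  zyg <- ifelse(stats::runif(nrow(idx)) <
                  p_hom_given_carrier[idx[, 1]], "hom_alt", "het")
  geno <- data.frame(variant_id = variants$variant_id[idx[, 1]],
                     sample_id = samples[idx[, 2]],
                     zygosity = zyg, stringsAsFactors = FALSE)

  # recessive spikes: plant compound-het pairs at the gene's biallelic rate
  rec_genes <- which(spec$recessive_spike)
  for (gi in rec_genes) {
    site_rows <- which(grid$gene_idx == gi)
    q <- 1 - prod(1 - grid$f[site_rows])
    p_ch <- min(1, spec$multiplier[gi] * q^2)
    hit <- which(stats::runif(spec$n_cases) < p_ch)
    for (s in hit) {
      sites <- sample(site_rows, 2L)
      geno <- rbind(geno, data.frame(
        variant_id = variants$variant_id[sites],
        sample_id = samples[s], zygosity = "het",
        stringsAsFactors = FALSE))
    }
  }
  # a spike may duplicate a sampled call; keep one record per (site, sample)
  geno <- geno[!duplicated(geno[, c("variant_id", "sample_id")]), ,
               drop = FALSE]

  # recurrent artifact sites: novel (absent from controls), clean balance,
  # damaging-looking annotations, planted in > recurrence_max samples
  rec_variants <- NULL
  if (spec$n_recurrent_sites > 0L) {
    gsel <- sample(spec$n_genes, spec$n_recurrent_sites, replace = TRUE)
    rec_variants <- data.frame(
      chrom = "1",
      pos = spec$n_genes * 10000L + 100L * seq_len(spec$n_recurrent_sites),
      ref = "A", alt = "G",
      gene = sprintf("G%04d", gsel),
      sift = stats::runif(spec$n_recurrent_sites, 0, 0.05),
      polyphen = stats::runif(spec$n_recurrent_sites, 0.91, 0.999),
      mutation_taster = "deleterious",
      predictsnp2_benign = 0L,
      maf = 0, stringsAsFactors = FALSE)
    rec_variants$variant_id <- variant_key(rec_variants$chrom,
                                           rec_variants$pos,
                                           rec_variants$ref,
                                           rec_variants$alt)
    for (i in seq_len(spec$n_recurrent_sites)) {
      ncarr <- sample(seq(spec$recurrence_max + 1L,
                          min(2L * spec$recurrence_max + 2L,
                              spec$n_cases)), 1L)
      geno <- rbind(geno, data.frame(
        variant_id = rec_variants$variant_id[i],
        sample_id = sample(samples, ncarr), zygosity = "het",
        stringsAsFactors = FALSE))
    }
    variants <- rbind(variants, rec_variants)
  }

  # read support
  ng <- nrow(geno)
  low <- stats::runif(ng) < spec$low_depth_fraction
  depth <- ifelse(low, sample(7:10, ng, replace = TRUE),
                  sample(20:100, ng, replace = TRUE))
  recurrent_ids <- if (is.null(rec_variants)) character(0) else
    rec_variants$variant_id
  artifact <- stats::runif(ng) < spec$artifact_fraction &
    !(geno$variant_id %in% recurrent_ids)
  geno$alt_reads <- sim_alt_reads(geno$zygosity, depth, artifact)
  geno$depth <- depth
  geno <- geno[, c("variant_id", "sample_id", "zygosity",
                   "alt_reads", "depth")]
  rownames(geno) <- NULL

  cohort <- cohort_table(variants, geno, samples)

  # --- truth bookkeeping (generator-side, independent of the filters) ---
  v <- cohort$variants
  func_pass <- ifelse(v$variant_class == "SNV",
                      !is.na(v$sift) & v$sift <= 0.05 &
                        v$polyphen >= 0.909 &
                        v$mutation_taster == "deleterious" &
                        v$predictsnp2_benign <= 1 & v$maf < 0.001,
                      v$maf < 0.001)
  func_pass[is.na(func_pass)] <- FALSE
  names(func_pass) <- v$variant_id
  ar_pass <- !artifact
  surv12 <- func_pass[geno$variant_id] & ar_pass
  carriers_after_qc <- tapply(geno$sample_id[surv12],
                              geno$variant_id[surv12],
                              function(s) length(unique(s)))
  too_recurrent <- names(carriers_after_qc)[carriers_after_qc >
                                              spec$recurrence_max]
  pair_survives <- surv12 & !(geno$variant_id %in% too_recurrent)

  truth <- list(
    variants = data.frame(
      variant_id = v$variant_id, gene = v$gene,
      damaging = unname(func_pass),
      recurrent_artifact = v$variant_id %in% recurrent_ids,
      passes_prioritization = v$variant_id %in%
        unique(geno$variant_id[pair_survives]),
      stringsAsFactors = FALSE),
    pairs = data.frame(
      variant_id = geno$variant_id, sample_id = geno$sample_id,
      artifact = artifact, survives = unname(pair_survives),
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene = sprintf("G%04d", seq_len(spec$n_genes)),
      multiplier = spec$multiplier,
      model = ifelse(spec$recessive_spike, "rec",
                     ifelse(spec$multiplier > 1, "dom", "null")),
      stringsAsFactors = FALSE))

  list(cohort = cohort, truth = truth)
}

#' Generate the matching population-control site summary
#'
#' Deterministic by default: AC = round(2 * control_n * f),
#' AN = 2 * control_n, nhom = round(control_n * f^2) per catalogue site, so
#' any case-vs-control discrepancy is attributable to case sampling alone.
#' `sampled = TRUE` instead draws AC and nhom binomially (seeded from the
#' spec), for studies of control-side noise. Recurrent-artifact sites are
#' novel and do not appear.
#'
#' @param spec a [cohort_sim_spec()].
#' @param sampled draw AC/nhom stochastically instead of rounding.
#' @return control summary data.frame as from [read_control_summary()].
#' @export
simulate_control_summary <- function(spec, sampled = FALSE) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  grid <- sim_site_grid(spec)
  an <- 2L * spec$control_n
  if (sampled) {
    set.seed(spec$seed + 1L)
    ac <- stats::rbinom(nrow(grid), an, grid$f)
    nhom <- pmin(stats::rbinom(nrow(grid), spec$control_n, grid$f^2),
                 ac %/% 2L)
  } else {
    ac <- round(an * grid$f)
    nhom <- round(spec$control_n * grid$f^2)
    nhom <- pmin(nhom, ac %/% 2L)
  }
  out <- data.frame(chrom = grid$chrom, pos = grid$pos,
                    ref = "A", alt = "G",
                    control_ac = as.integer(ac),
                    control_an = an,
                    control_nhom = as.integer(nhom),
                    gene = grid$gene,
                    stringsAsFactors = FALSE)
  out$variant_id <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out
}

#' Simulate a gene-set collection with an optional spiked term
#'
#' Builds `n_terms` random gene sets over a gene catalogue, plus (when
#' `spiked_genes` is given) one term containing exactly those genes —
#' the planted signal an overrepresentation scan should recover.
#'
#' @param genes character vector: the background gene catalogue.
#' @param n_terms number of random terms.
#' @param spiked_genes genes of the planted term (subset of `genes`), or
#'   `NULL` for a fully null collection.
#' @param term_size integer range of random term sizes.
#' @param seed RNG seed.
#' @return list: `collection` (a [gene_set_collection()]) and `truth`
#'   (per-term spiked flag).
#' @export
simulate_gene_sets <- function(genes, n_terms = 20L, spiked_genes = NULL,
                               term_size = c(10L, 30L), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(is.null(spiked_genes) || all(spiked_genes %in% genes))
  set.seed(seed)
  terms <- list()
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(term_size[1], min(term_size[2], length(genes))), 1L)
    terms[[sprintf("T%04d", i)]] <-
      list(name = sprintf("random term %d", i),
           genes = sample(genes, sz))
  }
  spiked <- rep(FALSE, length(terms))
  if (!is.null(spiked_genes)) {
    terms[["SPIKE"]] <- list(name = "planted term",
                             genes = unique(spiked_genes))
    spiked <- c(spiked, TRUE)
  }
  collection <- gene_set_collection(terms, genes)
  list(collection = collection,
       truth = data.frame(term_id = names(terms), spiked = spiked,
                          stringsAsFactors = FALSE))
}
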