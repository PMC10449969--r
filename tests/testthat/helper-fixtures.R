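# In-code fixtures and independent oracles shared across test files.

# A variant row with damaging defaults; override any field.
toy_variant <- function(pos, gene = "GENE1", ref = "A", alt = "G",
                        sift = 0.01, polyphen = 0.95,
                        mutation_taster = "deleterious",
                        predictsnp2_benign = 0L, maf = 0, chrom = "1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             sift = sift, polyphen = polyphen,
             mutation_taster = mutation_taster,
             predictsnp2_benign = predictsnp2_benign, maf = maf,
             stringsAsFactors = FALSE)
}

toy_call <- function(variant, sample_id, zygosity = "het",
                     alt_reads = 10L, depth = 20L) {
  data.frame(variant_id = paste(variant$chrom, variant$pos, variant$ref,
                                variant$alt, sep = ":"),
             sample_id = sample_id, zygosity = zygosity,
             alt_reads = alt_reads, depth = depth,
             stringsAsFactors = FALSE)
}

toy_control_row <- function(variant, ac, an = 251496L, nhom = 0L) {
  data.frame(chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
             alt = variant$alt, control_ac = ac, control_an = an,
             control_nhom = nhom,
             variant_id = paste(variant$chrom, variant$pos, variant$ref,
                                variant$alt, sep = ":"),
             stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric enumeration oracles for a 2x2 table
# [[a, b], [c, d]]: condition on margins, enumerate every admissible
# top-left cell. Independent of the package's phyper/fisher.test paths.
enum_fisher <- function(a, b, c, d, alternative = "greater") {
  K <- a + c          # carriers
  n <- a + b          # cases drawn
  M <- a + b + c + d
  kk <- max(0, n + K - M):min(n, K)
  pr <- choose(K, kk) * choose(M - K, n - kk) / choose(M, n)
  if (alternative == "greater") {
    sum(pr[kk >= a])
  } else {
    # two-sided by the probability-mass rule fisher.test uses
    sum(pr[pr <= pr[kk == a] * (1 + 1e-7)])
  }
}

# Step-up BH applied literally from its definition.
enum_bh <- function(p, m_total = length(p)) {
  o <- order(p)
  q <- numeric(length(p))
  sorted <- p[o]
  for (i in seq_along(sorted))
    q[i] <- min(1, min(sorted[seq(i, length(sorted))] * m_total /
                         seq(i, length(sorted))))
  out <- numeric(length(p))
  out[o] <- q
  out
}
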