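#' Fisher overrepresentation test for one gene set
#'
#' Tests whether the overlap k between a gene list (size n) and a term
#' (size K) departs from the n*K/M expected under uniform draws from a
#' background of M genes, via Fisher's exact test on
#' \[\[k, n-k\], \[K-k, M-n-K+k\]\]. Two-sided by default so that
#' under-representation is detectable; direction is the sign of k - n*K/M.
#'
#' @param gene_list character vector of query genes (subset of background).
#' @param term_genes character vector: the gene set.
#' @param background character vector: the gene universe.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return one-row data.frame: `k`, `n`, `K`, `M`, `expected`, `direction`,
#'   `fold`, `p_value`.
#' @export
ora_fisher <- function(gene_list, term_genes, background,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  M <- length(background)
  if (M == 0L) stop("empty background universe", call. = FALSE)
  gene_list <- unique(gene_list)
  missing <- setdiff(gene_list, background)
  if (length(missing))
    stop("genes in list but not in background: ",
         paste(missing, collapse = ", "), call. = FALSE)
  term_genes <- intersect(unique(term_genes), background)
  n <- length(gene_list)
  K <- length(term_genes)
  k <- length(intersect(gene_list, term_genes))
  expected <- n * K / M
  if (K == 0L || n == 0L) {
    return(data.frame(k = k, n = n, K = K, M = M, expected = expected,
                      direction = "under", fold = NA_real_, p_value = 1,
                      stringsAsFactors = FALSE))
  }
  tab <- matrix(c(k, n - k, K - k, M - n - K + k), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  data.frame(k = k, n = n, K = K, M = M, expected = expected,
             direction = if (k > expected) "over" else "under",
             fold = k / expected, p_value = min(p, 1),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, q_i = min_{j >= i} p_j * m_total / j,
#' clipped at 1, returned in input order. `m_total` may exceed the number of
#' p-values supplied, which adjusts a reported subset against the full
#' family of tests actually performed.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m_total total number of tests in the family
#'   (default `length(p)`).
#' @return adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m_total < length(p))
    stop("m_total must be at least length(p)", call. = FALSE)
  stats::p.adjust(p, method = "BH", n = m_total)
}

#' Gene-set overrepresentation scan
#'
#' Runs [ora_fisher()] for every term of a collection against its background,
#' adjusts across terms with [bh_adjust()], and ranks by p-value. Both over-
#' and under-represented terms are reported; `significant` flags FDR below
#' `alpha`.
#'
#' @param gene_list character vector of query genes.
#' @param collection a [gene_set_collection()].
#' @param alpha FDR significance threshold (default 0.05).
#' @param alternative passed to [ora_fisher()].
#' @return data.frame of class `enrichment_result`, one row per term, sorted
#'   by p-value: term_id, term_name, k, n, K, M, expected, direction, fold,
#'   p_value, fdr, significant.
#' @export
run_enrichment <- function(gene_list, collection, alpha = 0.05,
                           alternative = "two.sided") {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$terms)
  rows <- lapply(ids, function(id)
    ora_fisher(gene_list, collection$terms[[id]]$genes,
               collection$background, alternative = alternative))
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(k = integer(), n = integer(), K = integer(),
                      M = integer(), expected = numeric(),
                      direction = character(), fold = numeric(),
                      p_value = numeric())
    ids <- character(0)
  }
  out <- cbind(term_id = ids,
               term_name = vapply(collection$terms, `[[`, character(1),
                                  "name")[ids],
               out, stringsAsFactors = FALSE)
  out$fdr <- if (nrow(out)) bh_adjust(out$p_value) else numeric(0)
  out$significant <- out$fdr < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            alpha = alpha, alternative = alternative)
}

#' @method print enrichment_result
#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("Overrepresentation scan:", nrow(x), "terms;",
      sum(x$significant), "significant at FDR <",
      attr(x, "alpha"), "\n")
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("term_id", "term_name", "k", "K", "expected",
                           "direction", "fold", "p_value", "fdr")]
  df$expected <- signif(df$expected, 3)
  df$fold <- signif(df$fold, 3)
  df$p_value <- signif(df$p_value, 3)
  df$fdr <- signif(df$fdr, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
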