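#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{j = k..min(n, K)} C(K, j) C(N - K, n - j) / C(N, n)` —
#' the one-sided over-representation test.
#'
#' @param N background universe size.
#' @param K background genes carrying the term.
#' @param n genes tested (drawn).
#' @param k genes tested that carry the term.
#' @return p-value in (0, 1]; `p = 1` when `k = 0`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (k < 0 || K > N || n > N || k > min(n, K)) {
    stop("hypergeom_tail: invalid bounds (need 0 <= k <= min(n, K), K <= N, n <= N)")
  }
  min(1, sum(stats::dhyper(k:min(n, K), K, N - K, n)))
}

#' Term enrichment of a target gene set
#'
#' One-sided hypergeometric over-representation test per term, against an
#' explicit background universe. No multiple-testing correction is applied
#' by default (the enrichment call is at raw p <= alpha); opt-in
#' Benjamini-Hochberg q-values are reported alongside.
#'
#' @param target_genes character vector of genes of interest.
#' @param annotation data.frame: `gene`, `term_id`, `term_name`,
#'   `namespace`.
#' @param universe background gene universe (default: all genes in the
#'   annotation table).
#' @param alpha significance threshold on raw p (default 0.05).
#' @param bh also report Benjamini-Hochberg q-values (default FALSE).
#' @return data.frame sorted by p: `term_id`, `term_name`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_value`, `enriched`, and `q_value` when
#'   `bh = TRUE`.
#' @export
enrich <- function(target_genes, annotation, universe = NULL, alpha = 0.05,
                   bh = FALSE) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  target_genes <- unique(target_genes)
  if (!all(target_genes %in% universe)) {
    stop("enrich: target genes must be a subset of the universe")
  }
  if (!length(target_genes)) {
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(target_genes)
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  terms <- unique(ann[, c("term_id", "term_name", "namespace")])
  rows <- list()
  j <- 0L
  for (i in seq_len(nrow(terms))) {
    genes_t <- unique(ann$gene[ann$term_id == terms$term_id[i]])
    k <- sum(target_genes %in% genes_t)
    if (k < 1L) next
    j <- j + 1L
    rows[[j]] <- data.frame(
      term_id = terms$term_id[i], term_name = terms$term_name[i],
      namespace = terms$namespace[i], k = k, n = n,
      K = length(genes_t), N = N,
      p_value = hypergeom_tail(N, length(genes_t), n, k),
      stringsAsFactors = FALSE
    )
  }
  if (!j) {
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$enriched <- out$p_value <= alpha
  if (bh) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO-style classification of target genes by namespace
#'
#' Per namespace (molecular function, biological process, cellular
#' component, pathway), tabulates term assignments of the target genes;
#' a gene contributes once per term and percentages are over all term
#' assignments within the namespace (summing to 100 within each).
#'
#' @param target_genes character vector of genes.
#' @param annotation data.frame: `gene`, `term_id`, `term_name`,
#'   `namespace`.
#' @return data.frame: `namespace`, `term_id`, `term_name`, `gene_count`,
#'   `percent`.
#' @export
go_classify <- function(target_genes, annotation) {
  ann <- annotation[annotation$gene %in% target_genes, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term_id", "term_name", "namespace")])
  if (!nrow(ann)) {
    return(data.frame(namespace = character(), term_id = character(),
                      term_name = character(), gene_count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (ns in unique(ann$namespace)) {
    sub <- ann[ann$namespace == ns, , drop = FALSE]
    terms <- unique(sub[, c("term_id", "term_name")])
    cnt <- vapply(terms$term_id, function(t) {
      length(unique(sub$gene[sub$term_id == t]))
    }, 1L)
    out[[ns]] <- data.frame(
      namespace = ns, term_id = terms$term_id, term_name = terms$term_name,
      gene_count = cnt, percent = 100 * cnt / sum(cnt),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
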