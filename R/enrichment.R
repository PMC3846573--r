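# Hypergeometric pathway enrichment of DEG sets.
#
# With N annotated genes in the background, n of them differentially
# expressed, M annotated to a pathway and m of those differentially
# expressed, the enrichment p-value is the upper tail
#
#   p = P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)
#
# for X hypergeometric(N, M, n), evaluated by log-gamma summation of the
# upper tail (numerically identical to the complement form but immune
# to cancellation for small p).

#' Hypergeometric enrichment p-value P(X >= m)
#'
#' @param N background size (genes with pathway annotation)
#' @param n number of DEGs within the background
#' @param M genes annotated to the pathway
#' @param m DEGs annotated to the pathway
#' @return upper-tail probability in (0, 1]
#' @export
hypergeom_enrich_p <- function(N, n, M, m) {
  if (length(N) > 1 || length(n) > 1 || length(M) > 1 || length(m) > 1) {
    return(mapply(hypergeom_enrich_p, N, n, M, m))
  }
  for (v in c(N, n, M, m))
    if (v < 0 || v != floor(v)) stop("arguments must be non-negative integers")
  if (M > N || n > N) stop("infeasible: M and n must not exceed N")
  if (m > min(M, n)) stop("infeasible: m exceeds min(M, n)")
  if (m == 0) return(1)
  hi <- min(M, n)
  lo_support <- max(0, n + M - N)
  if (m <= lo_support) return(1) # below the support: the tail is everything
  i <- m:hi
  lterm <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, sum(sort(exp(lterm))))
}

#' Pathway enrichment of a DEG set
#'
#' Restricts the universe and DEG set to annotated genes, computes the
#' per-pathway upper-tail hypergeometric p-value, adjusts across tested
#' pathways (BH by default), and orders the table by total DEG count
#' descending, then p ascending. Pathways annotating fewer than 3
#' background genes are tested but flagged `low_power`.
#'
#' @param annotation data.frame with columns gene_id, pathway_id and
#'   optionally pathway_name
#' @param universe character vector: all genes eligible for calling
#'   (e.g. every tested gene)
#' @param degs character vector of differentially expressed genes
#'   (subset of `universe`)
#' @param de_calls optional data.frame (gene_id, call) used to split m
#'   into up/down counts per pathway
#' @param q_cut significance threshold on the adjusted p (Q) value;
#'   enriched means q strictly below the cut
#' @param method FDR method passed to [fdr_adjust()]
#' @return data.frame (class `enrichment_result`): pathway_id,
#'   pathway_name, M, m_up, m_down, m_total, p, q, enriched, low_power;
#'   attributes N and n carry the background sizes
#' @export
enrich_all <- function(annotation, universe, degs, de_calls = NULL,
                       q_cut = 0.05, method = "BH") {
  stopifnot(all(c("gene_id", "pathway_id") %in% names(annotation)))
  if (nrow(annotation) == 0) stop("empty pathway annotation")
  if (!all(degs %in% universe)) stop("degs must be a subset of universe")
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  annotated_genes <- unique(annotation$gene_id)
  N <- length(annotated_genes)
  deg_ann <- intersect(degs, annotated_genes)
  n <- length(deg_ann)
  up_set <- down_set <- character(0)
  if (!is.null(de_calls)) {
    up_set <- de_calls$gene_id[de_calls$call == "up"]
    down_set <- de_calls$gene_id[de_calls$call == "down"]
  }
  paths <- split(annotation, annotation$pathway_id)
  rows <- lapply(paths, function(pa) {
    members <- unique(pa$gene_id)
    m_genes <- intersect(members, deg_ann)
    data.frame(
      pathway_id = pa$pathway_id[1],
      pathway_name = if ("pathway_name" %in% names(pa))
        pa$pathway_name[1] else pa$pathway_id[1],
      M = length(members),
      m_up = length(intersect(m_genes, up_set)),
      m_down = length(intersect(m_genes, down_set)),
      m_total = length(m_genes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p <- hypergeom_enrich_p(rep(N, nrow(out)), rep(n, nrow(out)),
                              out$M, out$m_total)
  out$q <- fdr_adjust(out$p, method)
  out$enriched <- out$q < q_cut
  out$low_power <- out$M < 3
  out <- out[order(-out$m_total, out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "n") <- n
  class(out) <- c("enrichment_result", "data.frame")
  out
}
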