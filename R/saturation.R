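# Sequencing-depth saturation: how many genes are detected when only
# the first n of the library's retained tag reads are kept.

#' Subsampled gene-detection (saturation) curve
#'
#' The retained tag entries are expanded to read level (one element per
#' copy), subsampled without replacement at each depth — modelling
#' sequencing fewer reads from the same library — mapped through the
#' supplied index assignments, and the number of genes with at least one
#' assigned read is recorded. Tag-to-gene assignment is per-sequence and
#' depth-independent, so mapping the full library once and subsampling
#' assigned labels is exact. Replicate permutations are averaged.
#'
#' @param table a `tag_count_table`
#' @param mapping a `gene_expression` from [map_tags()] on that table
#' @param depths sorted vector of depths; default 10 evenly spaced
#'   depths ending at the full library
#' @param n_replicates random subsampling replicates to average
#' @param seed RNG seed
#' @return object of class `saturation_curve`: data.frame with
#'   tags_sampled, genes_detected (replicate mean), plus attributes
#'   n_replicates and seed
#' @export
saturation_curve <- function(table, mapping, depths = NULL,
                             n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(table, "tag_count_table"),
            inherits(mapping, "gene_expression"))
  n_reads <- sum(table$counts)
  if (n_reads == 0) stop("empty library")
  if (is.null(depths))
    depths <- unique(round(seq_len(10L) / 10 * n_reads))
  depths <- sort(unique(as.integer(depths)))
  if (max(depths) > n_reads)
    stop("depth exceeds library size (", n_reads, " retained reads)")
  # read-level gene labels; NA = retained but unassigned read
  gene_of <- stats::setNames(mapping$assignments$gene_id,
                             mapping$assignments$tag)
  labels <- rep(gene_of[names(table$counts)], times = table$counts)
  detected <- matrix(0, nrow = n_replicates, ncol = length(depths))
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      perm <- labels[sample.int(n_reads)]
      first <- which(!duplicated(perm, incomparables = NA) & !is.na(perm))
      detected[r, ] <- vapply(depths, function(d) sum(first <= d),
                              numeric(1))
    }
  })
  out <- data.frame(tags_sampled = depths,
                    genes_detected = colMeans(detected))
  attr(out, "n_replicates") <- n_replicates
  attr(out, "seed") <- seed
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Closed-form expected detection at depth n
#'
#' Sampling n reads without replacement from a library of `total` reads
#' in which gene g owns `counts[g]` assigned reads, the expected number
#' of detected genes is `sum_g 1 - C(total - counts_g, n) / C(total, n)`.
#' Used as the analytic oracle for [saturation_curve()].
#'
#' @param counts per-gene assigned read counts
#' @param total total reads in the library (assigned + unassigned)
#' @param n depth(s)
#' @return expected detected-gene count per depth
#' @export
expected_genes_detected <- function(counts, total, n) {
  vapply(n, function(d) {
    miss <- exp(lchoose(total - counts, d) - lchoose(total, d))
    sum(1 - miss)
  }, numeric(1))
}

#' Plateau test for a saturation curve
#'
#' TRUE iff the relative gain in detected genes over the final `window`
#' grid steps is below `epsilon` (default: < 0.1\% new genes over the
#' last 2 steps).
#'
#' @param curve a `saturation_curve` (or data.frame with genes_detected)
#' @param window number of trailing grid steps to compare across
#' @param epsilon relative-gain threshold
#' @return logical
#' @export
is_saturated <- function(curve, window = 2L, epsilon = 0.001) {
  g <- curve$genes_detected
  if (length(g) <= window)
    stop("curve must have more than `window` points")
  last <- g[length(g)]
  ref <- g[length(g) - window]
  if (ref <= 0) return(FALSE)
  (last - ref) / ref < epsilon
}
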