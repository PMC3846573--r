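# Virtual NlaIII digestion and tag-to-gene annotation.
#
# The reference index holds every CATG-anchored 21-mer on the sense
# strand of each transcript (the enzyme needs >= 17 nt downstream of the
# anchor to yield a full tag). Clean tags map to genes with at most one
# mismatch in the 17-nt variable region; a tag whose matches span more
# than one gene is discarded as ambiguous.

#' Scan a transcriptome for CATG tag sites
#'
#' @param seqs named character vector (or DNAStringSet) of transcripts
#' @return data.frame with gene_id, pos (1-based anchor start), rank
#'   (0 = 3'-most usable site, increasing towards the 5' end), tag
#'   (21-nt sequence)
#' @export
scan_tag_sites <- function(seqs) {
  seqs <- as_named_seqs(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcript IDs must be present and unique")
  hits <- gregexpr(TAG_ANCHOR, seqs, fixed = TRUE)
  lens <- nchar(seqs)
  pos_list <- lapply(seq_along(seqs), function(i) {
    pos <- hits[[i]]
    pos <- pos[pos > 0 & pos + TAG_LENGTH - 1L <= lens[i]]
    sort(pos, decreasing = TRUE) # rank 0 = 3'-most
  })
  n_sites <- lengths(pos_list)
  gene_idx <- rep(seq_along(seqs), n_sites)
  pos <- unlist(pos_list, use.names = FALSE)
  if (is.null(pos)) pos <- integer(0)
  out <- data.frame(
    gene_id = names(seqs)[gene_idx],
    pos = pos,
    rank = sequence(n_sites[n_sites > 0]) - 1L,
    tag = substring(seqs[gene_idx], pos, pos + TAG_LENGTH - 1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build the reference tag index by virtual digestion
#'
#' One entry per distinct (tag sequence, gene) pair; a tag occurring at
#' several sites of the same gene keeps its 3'-most (lowest) rank. Tags
#' shared between genes retain all gene IDs — ambiguity is resolved at
#' mapping time, by exclusion.
#'
#' @param transcripts transcriptome (DNAStringSet or named character)
#' @return object of class `tag_index`: list with `table` (data.table:
#'   tag, gene_id, rank, keyed by tag), `gene_ids`, `n_genes_with_sites`
#' @export
build_tag_index <- function(transcripts) {
  seqs <- as_named_seqs(transcripts)
  sites <- scan_tag_sites(seqs)
  dt <- data.table::as.data.table(sites[, c("tag", "gene_id", "rank")])
  dt <- dt[order(rank), .(rank = rank[1]), by = .(tag, gene_id)]
  data.table::setkey(dt, tag)
  structure(list(table = dt,
                 gene_ids = names(seqs),
                 n_genes_with_sites = length(unique(dt$gene_id))),
            class = "tag_index")
}

# all Hamming-distance-1 neighbours of each tag, varying only the 17-nt
# region after the CATG anchor; returns data.table(orig, variant)
tag_neighbours <- function(tags) {
  bases <- c("A", "C", "G", "T")
  pieces <- vector("list", TAG_VAR_LENGTH * 3L)
  k <- 0L
  for (pos in (nchar(TAG_ANCHOR) + 1L):TAG_LENGTH) {
    cur <- substr(tags, pos, pos)
    for (b in bases) {
      sel <- cur != b
      if (!any(sel)) next
      v <- tags[sel]
      substr(v, pos, pos) <- b
      k <- k + 1L
      pieces[[k]] <- data.table::data.table(orig = tags[sel], variant = v)
    }
  }
  data.table::rbindlist(pieces[seq_len(k)])
}

#' Map clean tags to genes
#'
#' Exact hits take precedence: a tag equal to an index key is assigned
#' to that key's gene iff the exact match set holds exactly one gene.
#' Tags with no exact hit are compared at Hamming distance 1 over the
#' 17-nt variable region (the CATG anchor is enzymatic and never
#' mismatched); again the union of hit genes must be a single gene.
#' Tags whose match set spans several genes are discarded as ambiguous;
#' a tag hitting several sites of one gene counts once for that gene.
#'
#' @param table a `tag_count_table` from [filter_tags()]
#' @param index a `tag_index` from [build_tag_index()]
#' @param max_mismatch 0 (exact only) or 1
#' @return object of class `gene_expression`: list with
#'   \describe{
#'     \item{genes}{data.frame gene_id, count, tpm (TPM = count /
#'       retained_tags x 1e6)}
#'     \item{assignments}{data.frame tag, gene_id, count for every
#'       assigned tag}
#'     \item{report}{counts: unique_tags, matched_unique_tags,
#'       matched_genes, matched_total_tags, retained_tags,
#'       ambiguous_tags}
#'   }
#' @export
map_tags <- function(table, index, max_mismatch = 1L) {
  stopifnot(inherits(table, "tag_count_table"), inherits(index, "tag_index"))
  if (!max_mismatch %in% c(0L, 1L))
    stop("max_mismatch must be 0 or 1")
  counts <- table$counts
  tags <- names(counts)
  idx <- index$table
  assigned <- data.table::data.table(tag = character(0),
                                     gene_id = character(0))
  ambiguous <- 0L
  if (length(tags) && nrow(idx)) {
    q <- data.table::data.table(tag = tags)
    ex <- idx[q, on = "tag", nomatch = NULL]
    if (nrow(ex)) {
      exact_sets <- ex[, .(n_genes = data.table::uniqueN(gene_id),
                           gene_id = gene_id[1]), by = tag]
    } else {
      exact_sets <- data.table::data.table(tag = character(0),
                                           n_genes = integer(0),
                                           gene_id = character(0))
    }
    assigned <- exact_sets[n_genes == 1L, .(tag, gene_id)]
    ambiguous <- sum(exact_sets$n_genes > 1L)
    if (max_mismatch >= 1L) {
      unmatched <- setdiff(tags, exact_sets$tag)
      if (length(unmatched)) {
        nb <- tag_neighbours(unmatched)
        hit <- idx[nb, on = c(tag = "variant"), nomatch = NULL]
        if (nrow(hit)) {
          mm_sets <- hit[, .(n_genes = data.table::uniqueN(gene_id),
                             gene_id = gene_id[1]), by = orig]
          assigned <- rbind(assigned,
                            mm_sets[n_genes == 1L,
                                    .(tag = orig, gene_id)])
          ambiguous <- ambiguous + sum(mm_sets$n_genes > 1L)
        }
      }
    }
  }
  assigned_df <- as.data.frame(assigned)
  assigned_df$count <- as.integer(counts[assigned_df$tag])
  retained <- table$ledger$retained_tags
  gene_counts <- if (nrow(assigned_df) > 0)
    stats::aggregate(count ~ gene_id, data = assigned_df, FUN = sum)
  else
    data.frame(gene_id = character(0), count = integer(0))
  gene_counts <- gene_counts[order(gene_counts$gene_id), , drop = FALSE]
  rownames(gene_counts) <- NULL
  gene_counts$tpm <- if (retained > 0)
    gene_counts$count / retained * 1e6 else rep(0, nrow(gene_counts))
  report <- list(
    library_id = table$library_id,
    unique_tags = length(tags),
    matched_unique_tags = nrow(assigned_df),
    matched_genes = nrow(gene_counts),
    matched_total_tags = sum(assigned_df$count),
    retained_tags = retained,
    ambiguous_tags = ambiguous
  )
  structure(list(genes = gene_counts, assignments = assigned_df,
                 report = report),
            class = "gene_expression")
}

#' Annotation percentage report
#'
#' @param report the `report` element of a [map_tags()] result, or any
#'   list with matched_unique_tags, unique_tags, matched_genes,
#'   matched_total_tags and retained_tags
#' @param n_reference_genes size of the reference gene set
#' @return list of percentages (half-up, 2 dp): matched_unique_pct,
#'   matched_gene_pct, matched_total_pct
#' @export
annotation_rates <- function(report, n_reference_genes) {
  for (f in c("matched_unique_tags", "unique_tags", "matched_genes",
              "matched_total_tags", "retained_tags"))
    if (is.null(report[[f]])) stop("report is missing field: ", f)
  if (report$unique_tags == 0 || n_reference_genes == 0 ||
      report$retained_tags == 0)
    stop("percentage undefined: zero denominator")
  list(
    matched_unique_pct = pct2(report$matched_unique_tags, report$unique_tags),
    matched_gene_pct = pct2(report$matched_genes, n_reference_genes),
    matched_total_pct = pct2(report$matched_total_tags, report$retained_tags)
  )
}
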