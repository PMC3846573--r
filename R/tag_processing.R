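# Raw-read to clean-tag filtering ladder.
#
# Mirrors the standard DGE QC report: total sequenced tags -> clean tags
# (drop reads containing N, adapter artifacts and, by default, reads not
# anchored by CATG) -> drop copy-number-1 tags -> retained tags and the
# unique-tag census.

#' Build a tag count table from raw reads
#'
#' Filtering ladder:
#' \enumerate{
#'   \item total: all input reads;
#'   \item clean: drop reads containing `N`, reads matching the adapter
#'     (exact prefix match of at least `min_adapter_match` nt), and —
#'     when `require_anchor` — reads not starting with `CATG`;
#'   \item singleton removal: tag sequences seen exactly once are
#'     excluded as likely sequencing artifacts;
#'   \item census: retained tags (copies) and unique tags (distinct
#'     sequences).
#' }
#'
#' @param reads character vector of 21-nt reads (or a named integer
#'   vector of pre-counted tags, names = sequences)
#' @param adapter adapter sequence for artifact detection
#' @param min_adapter_match minimum exact prefix length shared between a
#'   read and the adapter to call it an adapter artifact
#' @param require_anchor drop reads whose first 4 nt are not `CATG`
#'   (default TRUE: the anchor is part of every genuine tag)
#' @param library_id label carried through reports
#' @return object of class `tag_count_table`: list with `library_id`,
#'   `counts` (named integer vector, tag -> copy number, all >= 2) and
#'   `ledger` (total_tags, clean_tags, singleton_tags, retained_tags,
#'   unique_tags)
#' @export
filter_tags <- function(reads, adapter = GEX_ADAPTER_1,
                        min_adapter_match = 8L, require_anchor = TRUE,
                        library_id = "library") {
  if (is.numeric(reads) && !is.null(names(reads))) {
    counts0 <- reads
    total <- sum(counts0)
    seqs <- names(counts0)
  } else {
    reads <- as.character(reads)
    total <- length(reads)
    if (total) {
      tab <- table(reads)
      counts0 <- as.vector(tab)
      seqs <- names(tab)
    } else {
      counts0 <- integer(0)
      seqs <- character(0)
    }
  }
  if (length(seqs)) {
    ad_len <- max(min_adapter_match, 1L)
    ad_prefix <- substr(adapter, 1L, ad_len)
    bad <- grepl("N", seqs, fixed = TRUE) |
      startsWith(seqs, ad_prefix)
    if (require_anchor)
      bad <- bad | !startsWith(seqs, TAG_ANCHOR)
    counts0 <- counts0[!bad]
    seqs <- seqs[!bad]
  }
  clean <- sum(counts0)
  singleton <- sum(counts0 == 1)
  keep <- counts0 >= 2
  counts <- stats::setNames(as.integer(counts0[keep]), seqs[keep])
  ledger <- list(
    total_tags = as.numeric(total),
    clean_tags = as.numeric(clean),
    singleton_tags = as.numeric(singleton),
    retained_tags = as.numeric(clean - singleton),
    unique_tags = length(counts)
  )
  structure(list(library_id = library_id, counts = counts,
                 ledger = ledger),
            class = "tag_count_table")
}

#' Assemble a tag table from printed ledger totals
#'
#' For ledger arithmetic on published QC numbers (no sequences
#' available): retained = clean - singletons; unique is optional.
#'
#' @param total_tags,clean_tags,singleton_tags printed counts
#' @param unique_tags optional printed unique-tag count
#' @param library_id label
#' @return a `tag_count_table` with an empty `counts` slot
#' @export
tag_ledger <- function(total_tags, clean_tags, singleton_tags,
                       unique_tags = NA_integer_, library_id = "library") {
  if (clean_tags > total_tags || singleton_tags > clean_tags)
    stop("inconsistent ledger counts")
  structure(list(
    library_id = library_id,
    counts = stats::setNames(integer(0), character(0)),
    ledger = list(total_tags = total_tags, clean_tags = clean_tags,
                  singleton_tags = singleton_tags,
                  retained_tags = clean_tags - singleton_tags,
                  unique_tags = unique_tags)
  ), class = "tag_count_table")
}

#' Unique-tag counts above copy-number thresholds
#'
#' Reproduces the "unique tags copy number > k" strata of a DGE QC
#' table.
#'
#' @param table a `tag_count_table`
#' @param thresholds positive, sorted integer thresholds
#' @return named integer vector, one count per threshold (">k")
#' @export
copy_number_strata <- function(table, thresholds = c(5L, 10L, 20L, 50L, 100L)) {
  stopifnot(inherits(table, "tag_count_table"))
  if (any(thresholds < 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be non-negative and strictly increasing")
  out <- vapply(thresholds, function(t) sum(table$counts > t), integer(1))
  stats::setNames(out, paste0(">", thresholds))
}

#' Retained / useless percentage report
#'
#' `retained_pct` = retained / total x 100; `useless_pct` = (total -
#' retained) / total x 100. Both computed from raw counts and rounded
#' half-up to 2 decimals (matching how such tables are printed), never
#' by subtracting rounded values.
#'
#' @param table a `tag_count_table` (ledger populated)
#' @return list with `retained_pct` and `useless_pct`
#' @export
library_summary <- function(table) {
  stopifnot(inherits(table, "tag_count_table"))
  led <- table$ledger
  if (led$total_tags == 0)
    stop("percentage undefined: empty library (total_tags = 0)")
  list(
    retained_pct = pct2(led$retained_tags, led$total_tags),
    useless_pct = pct2(led$total_tags - led$retained_tags, led$total_tags)
  )
}

#' Write / read a tag count table as 2-column TSV
#' @param table a `tag_count_table`
#' @param path TSV path; a sibling `.ledger.json` carries the ledger
#' @export
write_tags_tsv <- function(table, path) {
  df <- data.frame(tag = names(table$counts),
                   count = as.integer(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table$ledger,
                       paste0(tools::file_path_sans_ext(path), ".ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tags_tsv
#' @param library_id label for the re-read table
#' @export
read_tags_tsv <- function(path, library_id = "library") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  ledger_path <- paste0(tools::file_path_sans_ext(path), ".ledger.json")
  counts <- stats::setNames(df$count, df$tag)
  if (file.exists(ledger_path)) {
    ledger <- jsonlite::read_json(ledger_path, simplifyVector = TRUE)
  } else {
    ledger <- list(total_tags = sum(counts), clean_tags = sum(counts),
                   singleton_tags = 0, retained_tags = sum(counts),
                   unique_tags = length(counts))
  }
  structure(list(library_id = library_id, counts = counts, ledger = ledger),
            class = "tag_count_table")
}
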