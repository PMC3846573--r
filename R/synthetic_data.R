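# Synthetic DGE tag-library generator.
#
# Emulates NlaIII-anchored Illumina tag profiling of two unreplicated
# libraries (control CO, treated DS): transcripts are cut at CATG sites,
# the 3'-most site dominates but earlier sites leak tags with
# geometrically decaying weight (incomplete digestion), and raw 21-nt
# reads carry per-base substitution noise, ambiguous N bases, and a
# fraction of adapter-only ligation artifacts.

#' Tag geometry constants
#'
#' A DGE tag is the CATG anchor plus the 17 nt immediately downstream of
#' it, 21 nt in total.
#' @name tag-geometry
#' @keywords internal
NULL

TAG_LENGTH <- 21L
TAG_ANCHOR <- "CATG"
TAG_VAR_LENGTH <- 17L

#' Illumina GEX adapter-1 sequence used for adapter-only artifact reads
#'
#' Adapter-only reads are emitted as this sequence truncated (or padded
#' with A) to the 21-nt read length. The exact sequence is a stated
#' constant of the simulation, not an inference target.
#' @export
GEX_ADAPTER_1 <- "GTTCAGAGTTCTACAGTCCGACGATC"

adapter_read <- function(adapter = GEX_ADAPTER_1, width = TAG_LENGTH) {
  s <- substr(adapter, 1L, width)
  if (nchar(s) < width)
    s <- paste0(s, strrep("A", width - nchar(s)))
  s
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic two-library DGE experiment.
#' Defaults describe a small but realistic desk-scale experiment: 2000
#' genes, one million tags per library (the real libraries hold ~4.7-4.8
#' M), 10\% of genes differentially expressed with fold changes 2/4/8 and
#' reciprocals, log-normal baseline abundance (sdlog 1.5, the typical
#' spread of bulk expression), Illumina-like per-base substitution and N
#' rates of 1e-3, 0.5\% adapter-only reads, and digestion decay 0.2 (a
#' non-3'-most site is sampled at 20\% the weight of the site one rank
#' closer to the 3' end).
#'
#' @param n_genes number of transcripts in the toy transcriptome
#' @param length_range integer pair, transcript length bounds in nt
#'   (minimum >= 25 so a CATG + 17 nt tag always fits)
#' @param n_tags_per_library reads drawn per library
#' @param frac_de fraction of genes with a planted fold change
#' @param fold_change_set positive fold changes (DS/CO) assigned to DE
#'   genes, cycled in order
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   relative baseline transcript abundance
#' @param digestion_decay relative sampling weight of CATG site rank r
#'   (3'-most = 0) is `digestion_decay^r`, in (0, 1]
#' @param error_rate per-base substitution probability
#' @param n_rate per-base probability of an ambiguous N call
#' @param adapter_rate fraction of reads replaced by adapter-only sequence
#' @param seed master RNG seed; every stage derives its own sub-stream
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_genes = 2000L,
                       length_range = c(300L, 3000L),
                       n_tags_per_library = 1e6,
                       frac_de = 0.1,
                       fold_change_set = c(2, 4, 8, 1 / 2, 1 / 4, 1 / 8),
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.5,
                       digestion_decay = 0.2,
                       error_rate = 0.001,
                       n_rate = 0.001,
                       adapter_rate = 0.005,
                       seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  if (n_genes < 1) stop("n_genes must be positive")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1] > length_range[2])
    stop("length_range must be an ordered integer pair")
  if (length_range[1] < TAG_LENGTH + 4L)
    stop("length_range minimum must be >= 25 nt to host a CATG tag site")
  stopifnot_scalar_count(n_tags_per_library, "n_tags_per_library")
  for (r in c(frac_de, error_rate, n_rate, adapter_rate))
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1)
      stop("frac_de and all rates must lie in [0, 1]")
  if (!is.numeric(digestion_decay) || digestion_decay <= 0 ||
      digestion_decay > 1)
    stop("digestion_decay must lie in (0, 1]")
  if (any(fold_change_set <= 0)) stop("fold changes must be positive")
  structure(list(
    n_genes = as.integer(n_genes),
    length_range = length_range,
    n_tags_per_library = as.integer(n_tags_per_library),
    frac_de = frac_de,
    fold_change_set = fold_change_set,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    digestion_decay = digestion_decay,
    error_rate = error_rate,
    n_rate = n_rate,
    adapter_rate = adapter_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a toy transcriptome
#'
#' Draws `n_genes` uniform-random DNA sequences with lengths uniform on
#' `length_range`; any sequence lacking a CATG with at least 17 nt
#' downstream gets one implanted at a random valid position, so every
#' transcript carries at least one tag site. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()]
#' @return a named [Biostrings::DNAStringSet] (gene_0001, gene_0002, ...)
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    total <- sum(lens)
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    big <- paste(bases, collapse = "")
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- substring(big, starts, ends)
    # implant an anchor where the random sequence has no usable site
    need <- !vapply(seqs, has_tag_site, logical(1), USE.NAMES = FALSE)
    if (any(need)) {
      for (i in which(need)) {
        pos <- sample.int(lens[i] - TAG_LENGTH + 1L, 1L)
        substr(seqs[i], pos, pos + 3L) <- TAG_ANCHOR
      }
    }
    names(seqs) <- sprintf("gene_%04d", seq_len(n))
    Biostrings::DNAStringSet(seqs)
  })
}

has_tag_site <- function(seq) {
  hits <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1]]
  any(hits > 0 & hits + TAG_LENGTH - 1L <= nchar(seq))
}

#' Plant a per-gene expression truth table
#'
#' Baseline abundances are log-normal; a `frac_de` fraction of genes
#' (rounded) receives fold changes from `fold_change_set`, cycled in
#' order over the sampled DE genes; all others have fold 1.
#'
#' @param config a [sim_config()]
#' @param gene_ids gene identifiers; default matches
#'   [generate_transcriptome()] naming
#' @return data.frame with columns gene_id, baseline_expr, fold_change,
#'   is_de (the `SimulationTruth` table)
#' @export
plant_truth <- function(config,
                        gene_ids = sprintf("gene_%04d", seq_len(config$n_genes))) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(gene_ids)
  with_seed(derive_seed(config$seed, 2L), {
    baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    fold <- rep(1, n)
    n_de <- round(config$frac_de * n)
    if (n_de > 0) {
      de_idx <- sample.int(n, n_de)
      fold[de_idx] <- rep_len(config$fold_change_set, n_de)
    }
    data.frame(gene_id = gene_ids, baseline_expr = baseline,
               fold_change = fold, is_de = fold != 1,
               stringsAsFactors = FALSE)
  })
}

#' Simulate two raw tag libraries
#'
#' Per-read generative model, per library: (i) pick a gene proportional
#' to expression (baseline for CO, baseline x fold for DS) among genes
#' that carry at least one tag site; (ii) pick a CATG site within the
#' gene with weight `digestion_decay^rank` normalized over that gene's
#' sites (rank 0 = 3'-most); (iii) corrupt: with probability
#' `adapter_rate` emit an adapter-only read, otherwise convert each base
#' to N with probability `n_rate` and then substitute each remaining
#' base with probability `error_rate`. Exactly `n_tags_per_library`
#' reads per library; deterministic under `config$seed`.
#'
#' @param transcripts transcriptome ([Biostrings::DNAStringSet] or named
#'   character vector)
#' @param truth truth table from [plant_truth()]
#' @param config a [sim_config()]
#' @return object of class `tag_libraries`: list with `reads` (list of
#'   character vectors CO/DS), `truth`, `config`, and `site_draws`
#'   (per-library per-read gene assignment counts, for oracle tests)
#' @export
simulate_libraries <- function(transcripts, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- as_named_seqs(transcripts)
  if (length(seqs) == 0) stop("empty transcriptome")
  if (!all(truth$gene_id %in% names(seqs)))
    stop("every truth gene_id must appear in the transcriptome")
  sites <- scan_tag_sites(seqs)
  expr <- stats::setNames(truth$baseline_expr, truth$gene_id)
  fold <- stats::setNames(truth$fold_change, truth$gene_id)
  # per-site sampling weight: gene expression x normalized site weight
  site_w <- config$digestion_decay^sites$rank
  norm <- stats::ave(site_w, sites$gene_id, FUN = sum)
  site_w <- site_w / norm
  out_reads <- list()
  draws <- list()
  conds <- c(CO = 3L, DS = 4L)
  for (cond in names(conds)) {
    gexpr <- expr[sites$gene_id]
    if (cond == "DS") gexpr <- gexpr * fold[sites$gene_id]
    prob <- gexpr * site_w
    site_gene <- match(sites$gene_id, names(seqs))
    lib <- with_seed(derive_seed(config$seed, conds[[cond]]), {
      idx <- sample.int(nrow(sites), config$n_tags_per_library,
                        replace = TRUE, prob = prob)
      reads <- sites$tag[idx]
      gene_counts <- stats::setNames(
        tabulate(site_gene[idx], nbins = length(seqs)), names(seqs))
      reads <- corrupt_reads(reads, config)
      list(reads = reads, gene_counts = gene_counts)
    })
    out_reads[[cond]] <- lib$reads
    draws[[cond]] <- lib$gene_counts
  }
  structure(list(reads = out_reads, truth = truth, config = config,
                 site_draws = draws),
            class = "tag_libraries")
}

# adapter replacement, per-base N calls, per-base substitutions
corrupt_reads <- function(reads, config) {
  n <- length(reads)
  if (config$adapter_rate > 0) {
    is_ad <- stats::runif(n) < config$adapter_rate
    if (any(is_ad)) reads[is_ad] <- adapter_read()
  } else {
    is_ad <- logical(n)
  }
  target <- which(!is_ad)
  if (length(target) && config$n_rate > 0)
    reads[target] <- mutate_bases(reads[target], config$n_rate, to_n = TRUE)
  if (length(target) && config$error_rate > 0)
    reads[target] <- mutate_bases(reads[target], config$error_rate,
                                  to_n = FALSE)
  reads
}

# flip each base with probability `rate`; to_n replaces with "N",
# otherwise with a uniformly chosen different base (N bases are skipped)
mutate_bases <- function(reads, rate, to_n) {
  nhit <- stats::rbinom(length(reads), TAG_LENGTH, rate)
  hit <- which(nhit > 0)
  if (!length(hit)) return(reads)
  chars <- strsplit(reads[hit], "", fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hit)) {
    pos <- sample.int(TAG_LENGTH, nhit[hit[j]])
    for (p in pos) {
      cur <- chars[[j]][p]
      if (to_n) {
        chars[[j]][p] <- "N"
      } else if (cur != "N") {
        chars[[j]][p] <- sample(setdiff(bases, cur), 1L)
      }
    }
  }
  reads[hit] <- vapply(chars, paste, character(1), collapse = "")
  reads
}

#' Write simulated reads as FASTQ
#'
#' Dummy quality "I" (Phred 40) for every base.
#' @param reads character vector of 21-nt reads
#' @param path output file
#' @export
write_tag_fastq <- function(reads, path) {
  x <- Biostrings::BStringSet(reads)
  names(x) <- sprintf("read_%07d", seq_along(reads))
  qual <- Biostrings::BStringSet(rep(strrep("I", TAG_LENGTH), length(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read 21-nt tag reads from FASTQ
#' @param path FASTQ file
#' @return character vector of reads
#' @export
read_tag_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write / read a truth table
#' @param truth truth data.frame
#' @param path TSV path
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
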