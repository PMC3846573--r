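as_table <- function(counts, retained = sum(counts)) {
  structure(list(library_id = "T", counts = counts,
                 ledger = list(total_tags = retained, clean_tags = retained,
                               singleton_tags = 0, retained_tags = retained,
                               unique_tags = length(counts))),
            class = "tag_count_table")
}

test_that("virtual digestion produces exactly the usable anchored 21-mers", {
  tx <- c(g1 = paste0("AAA", "CATG", strrep("A", 17)))
  idx <- build_tag_index(tx)
  expect_equal(nrow(idx$table), 1L)
  expect_equal(idx$table$rank, 0L)
  expect_equal(idx$table$tag, paste0("CATG", strrep("A", 17)))
  # a site with only 10 nt downstream yields no key
  tx2 <- c(g1 = paste0(strrep("T", 30), "CATG", strrep("A", 10)))
  expect_equal(nrow(build_tag_index(tx2)$table), 0L)
  expect_error(build_tag_index(c(a = "CATGAAA", a = "CATGCCC")), "unique")
})

test_that("index key multiset equals the regex oracle on a synthetic transcriptome", {
  cfg <- sim_config(n_genes = 30, seed = 37)
  tx <- generate_transcriptome(cfg)
  idx <- build_tag_index(tx)
  # oracle: regex scan per sequence, dedupe (tag, gene) pairs
  oracle <- do.call(rbind, lapply(names(tx), function(g) {
    s <- as.character(tx[[g]])
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits + 20 <= nchar(s)]
    if (!length(hits)) return(NULL)
    unique(data.frame(gene_id = g, tag = substring(s, hits, hits + 20)))
  }))
  got <- as.data.frame(idx$table)[, c("gene_id", "tag")]
  o <- oracle[order(oracle$gene_id, oracle$tag), ]
  g <- got[order(got$gene_id, got$tag), ]
  rownames(o) <- rownames(g) <- NULL
  expect_equal(g, o)
  # ranks are 0-based from the 3' end within each gene
  expect_true(all(idx$table$rank >= 0))
})

test_that("mapping applies exact precedence and multi-gene exclusion", {
  v <- rand_vars(4, 41)
  shared <- mk_tag(v[1])
  solo <- mk_tag(v[2])
  near <- mk_tag(v[3])
  tx <- c(
    G1 = paste0(solo, "TT", shared),
    G2 = paste0(shared, "GG", mk_tag(v[4]))
  )
  idx <- build_tag_index(tx)
  mut <- near
  substr(mut, 21, 21) <- if (substr(mut, 21, 21) == "A") "C" else "A"
  tab <- as_table(stats::setNames(c(5L, 7L, 3L), c(solo, shared, mut)))
  res <- map_tags(tab, idx)
  # solo: unique exact hit; shared: exact in both genes -> discarded;
  # mut: no exact hit anywhere and no 1-mismatch neighbour in the index
  expect_equal(res$assignments$tag, solo)
  expect_equal(res$assignments$gene_id, "G1")
  expect_equal(res$report$ambiguous_tags, 1L)
  expect_equal(res$genes$count, 5L)

  # one-mismatch rescue: mutate solo in the variable region only
  mm <- solo
  substr(mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                substr(mm, 10, 10))[1]
  tab2 <- as_table(stats::setNames(4L, mm))
  res2 <- map_tags(tab2, idx)
  expect_equal(res2$assignments$gene_id, "G1")
  # with max_mismatch = 0 the same tag stays unmapped
  expect_equal(nrow(map_tags(tab2, idx, max_mismatch = 0L)$assignments), 0L)

  # exact precedence: a unique exact hit wins even when another gene's
  # key sits at Hamming distance 1
  k1 <- mk_tag(strrep("A", 17))
  k2 <- k1; substr(k2, 8, 8) <- "G"
  idx2 <- build_tag_index(c(A = paste0("GG", k1), B = paste0("GG", k2)))
  res3 <- map_tags(as_table(stats::setNames(6L, k1)), idx2)
  expect_equal(res3$assignments$gene_id, "A")
})

test_that("one-mismatch assignment agrees with a brute-force Hamming oracle", {
  cfg <- sim_config(n_genes = 25, seed = 43)
  tx <- generate_transcriptome(cfg)
  idx <- build_tag_index(tx)
  keys <- idx$table$tag
  # queries: real keys, variable-region mutants, and random tags
  qs <- with_test_seed(47, {
    picks <- sample(keys, 30)
    muts <- vapply(sample(keys, 30), function(t) {
      p <- sample(5:21, 1)
      substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(t, p, p)), 1)
      t
    }, "")
    unique(c(picks, muts, vapply(rand_vars(20, 53), mk_tag, "")))
  })
  tab <- as_table(stats::setNames(rep(2L, length(qs)), qs))
  res <- map_tags(tab, idx)
  got <- stats::setNames(res$assignments$gene_id, res$assignments$tag)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (q in qs) {
    d <- vapply(keys, ham, numeric(1), a = q)
    exact_genes <- unique(idx$table$gene_id[d == 0])
    cand <- if (length(exact_genes)) exact_genes else {
      # mismatches only count within the variable region
      ok <- d == 1 & substr(keys, 1, 4) == substr(q, 1, 4) &
        substr(q, 1, 4) == "CATG"
      unique(idx$table$gene_id[ok])
    }
    if (length(cand) == 1) expect_equal(unname(got[q]), cand)
    else expect_false(q %in% names(got))
  }
})

test_that("TPM normalization identity holds exactly", {
  s <- small_sim(n_genes = 30, n_tags = 2e4, seed = 59)
  tab <- filter_tags(s$libs$reads$CO)
  idx <- build_tag_index(s$tx)
  res <- map_tags(tab, idx)
  expect_equal(sum(res$genes$tpm),
               res$report$matched_total_tags /
                 res$report$retained_tags * 1e6)
  expect_lte(res$report$matched_total_tags, tab$ledger$retained_tags)
  # no tag contributes to more than one gene
  expect_equal(anyDuplicated(res$assignments$tag), 0L)
})

test_that("noise-free single-site simulation reproduces the planted draw counts", {
  cfg <- sim_config(n_genes = 10, n_tags_per_library = 1e5,
                    digestion_decay = 1e-9, error_rate = 0, n_rate = 0,
                    adapter_rate = 0, seed = 61)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  libs <- simulate_libraries(tx, truth, cfg)
  tab <- filter_tags(libs$reads$CO)
  res <- map_tags(tab, build_tag_index(tx))
  expect_equal(res$report$ambiguous_tags, 0L)
  draws <- libs$site_draws$CO[libs$site_draws$CO > 0]
  got <- stats::setNames(res$genes$count, res$genes$gene_id)
  expect_equal(got[order(names(got))], draws[order(names(draws))])
})

test_that("annotation rate arithmetic is exact on constructed reports", {
  report <- list(matched_unique_tags = 50, unique_tags = 200,
                 matched_genes = 30, matched_total_tags = 600,
                 retained_tags = 1000)
  r <- annotation_rates(report, 60)
  expect_equal(r, list(matched_unique_pct = 25, matched_gene_pct = 50,
                       matched_total_pct = 60))
  report$matched_unique_tags <- 200
  expect_equal(annotation_rates(report, 60)$matched_unique_pct, 100)
  expect_error(annotation_rates(list(matched_unique_tags = 1), 10),
               "missing field")
})
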