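test_that("transcriptome generation is seed-deterministic and writes identical FASTA", {
  cfg <- sim_config(n_genes = 10, n_tags_per_library = 100, seed = 1)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(tx1, f1)
  Biostrings::writeXStringSet(tx2, f2)
  expect_identical(readLines(f1), readLines(f2))
  tx3 <- generate_transcriptome(sim_config(n_genes = 10, seed = 2))
  expect_false(identical(as.character(tx1), as.character(tx3)))
})

test_that("every generated transcript hosts at least one usable CATG site", {
  cfg <- sim_config(n_genes = 100, length_range = c(25, 60), seed = 3)
  tx <- generate_transcriptome(cfg)
  expect_length(tx, 100)
  seqs <- as.character(tx)
  expect_true(all(grepl("^[ACGT]+$", seqs)))
  expect_true(all(vapply(seqs, regex_tag_count, numeric(1)) >= 1))
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(length_range = c(10, 40)), "25")
  expect_error(sim_config(error_rate = 1.2), "rates")
  expect_error(sim_config(digestion_decay = 0), "digestion_decay")
  expect_error(sim_config(fold_change_set = c(2, -1)), "positive")
})

test_that("site scan matches an independent regex oracle", {
  cfg <- sim_config(n_genes = 40, seed = 5)
  tx <- generate_transcriptome(cfg)
  sites <- scan_tag_sites(tx)
  per_gene <- table(factor(sites$gene_id, levels = names(tx)))
  oracle <- vapply(as.character(tx), regex_tag_count, numeric(1))
  expect_equal(as.numeric(per_gene), unname(oracle))
  expect_true(all(startsWith(sites$tag, "CATG")))
  expect_true(all(nchar(sites$tag) == 21))
})

test_that("noise-free decay->0 limit emits only 3'-most reference tags", {
  cfg <- sim_config(n_genes = 20, n_tags_per_library = 5000,
                    digestion_decay = 1e-12, error_rate = 0, n_rate = 0,
                    adapter_rate = 0, seed = 7)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  libs <- simulate_libraries(tx, truth, cfg)
  sites <- scan_tag_sites(tx)
  rank0 <- sites$tag[sites$rank == 0]
  for (lib in c("CO", "DS")) {
    expect_length(libs$reads[[lib]], 5000)
    expect_true(all(libs$reads[[lib]] %in% rank0))
  }
})

test_that("null symmetry: fold 1 gives matching per-tag frequencies", {
  cfg <- sim_config(n_genes = 1, frac_de = 0, n_tags_per_library = 2e4,
                    error_rate = 0, n_rate = 0, adapter_rate = 0, seed = 9)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  libs <- simulate_libraries(tx, truth, cfg)
  co <- table(libs$reads$CO)
  ds <- table(libs$reads$DS)
  tags <- union(names(co), names(ds))
  n <- cfg$n_tags_per_library
  for (tg in tags) {
    x <- ifelse(tg %in% names(co), co[[tg]], 0)
    y <- ifelse(tg %in% names(ds), ds[[tg]], 0)
    p_hat <- (x + y) / (2 * n)
    bound <- 4 * sqrt(2 * n * p_hat * (1 - p_hat)) # 4 sigma on x - y
    expect_lt(abs(x - y), max(bound, 30))
  }
})

test_that("a planted fold change is recovered in raw count ratios", {
  # one gene with fold 4 at ~1% baseline share, deep libraries
  cfg <- sim_config(n_genes = 10, frac_de = 0, n_tags_per_library = 1e6,
                    error_rate = 0, n_rate = 0, adapter_rate = 0, seed = 13)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  truth$baseline_expr <- rep(1, 10)
  truth$baseline_expr[1] <- 9 / 99 # share 0.01 of the CO library
  truth$fold_change[1] <- 4
  truth$is_de[1] <- TRUE
  libs <- simulate_libraries(tx, truth, cfg)
  x <- libs$site_draws$CO[["gene_0001"]]
  y <- libs$site_draws$DS[["gene_0001"]]
  # DS share of gene 1: 4*b1 / (sum + 3*b1)
  b1 <- truth$baseline_expr[1]; tot <- sum(truth$baseline_expr)
  p_co <- b1 / tot
  p_ds <- 4 * b1 / (tot + 3 * b1)
  for (obs_exp in list(c(x, p_co), c(y, p_ds))) {
    se <- sqrt(1e6 * obs_exp[2] * (1 - obs_exp[2]))
    expect_lt(abs(obs_exp[1] - 1e6 * obs_exp[2]), 4 * se)
  }
  ratio <- (y / 1e6 / p_ds) / (x / 1e6 / p_co) * 4 # ~4 after renormalising
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.6)
})

test_that("read conservation and corruption accounting hold", {
  cfg <- sim_config(n_genes = 30, n_tags_per_library = 5e4,
                    error_rate = 0, n_rate = 0.01, adapter_rate = 0.02,
                    seed = 17)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  libs <- simulate_libraries(tx, truth, cfg)
  reads <- libs$reads$CO
  expect_length(reads, 5e4)
  ad <- startsWith(reads, substr(GEX_ADAPTER_1, 1, 21))
  expect_lt(abs(mean(ad) - 0.02), 4 * sqrt(0.02 * 0.98 / 5e4))
  n_frac <- mean(grepl("N", reads[!ad], fixed = TRUE))
  expected <- 1 - (1 - 0.01)^21
  expect_lt(abs(n_frac - expected), 4 * sqrt(expected * (1 - expected) / 5e4))
})

test_that("libraries are deterministic under the config seed", {
  s <- small_sim(n_genes = 10, n_tags = 2000, seed = 19)
  libs2 <- simulate_libraries(s$tx, s$truth, s$cfg)
  expect_identical(s$libs$reads, libs2$reads)
})

test_that("FASTQ round trip preserves reads", {
  s <- small_sim(n_genes = 5, n_tags = 500, seed = 21)
  f <- tempfile(fileext = ".fastq")
  write_tag_fastq(s$libs$reads$CO, f)
  back <- read_tag_fastq(f)
  expect_equal(unname(back), s$libs$reads$CO)
})
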