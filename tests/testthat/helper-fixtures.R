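# Shared fixtures and oracles, built in code at test time.

# a valid 21-nt tag with a fixed variable region
mk_tag <- function(var = strrep("A", 17)) {
  stopifnot(nchar(var) == 17)
  paste0("CATG", var)
}

# random 17-nt variable regions under a local seed
rand_vars <- function(n, seed = 1) {
  with_test_seed(seed, replicate(n, paste(
    sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# run the exact-arithmetic python oracle for the two-library statistic;
# results cached per (xmax, ymax) for the session
ac_oracle_cache <- new.env(parent = emptyenv())
run_ac_oracle <- function(xmax, ymax) {
  key <- paste(xmax, ymax, sep = "_")
  if (!is.null(ac_oracle_cache[[key]])) return(ac_oracle_cache[[key]])
  script <- system.file("oracle", "ac_oracle.py", package = "tagdge")
  stopifnot(nzchar(script))
  out <- tempfile(fileext = ".tsv")
  status <- system2("python", c(script, xmax, ymax, out))
  stopifnot(status == 0)
  res <- utils::read.delim(out)
  ac_oracle_cache[[key]] <- res
  res
}

# exact hypergeometric tail enumeration: all arithmetic on integers that
# stay below 2^53 for N <= 30 (each term and the sum are bounded by
# C(N, n) <= C(30, 15) ~ 1.6e8)
enum_hyper_upper <- function(N, n, M, m) {
  i <- 0:min(M, n)
  mass <- choose(M, i) * choose(N - M, n - i)
  sum(mass[i >= m]) / choose(N, n)
}

# regex-based independent count of CATG-anchored 21-mers in a sequence
regex_tag_count <- function(seq) {
  hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  sum(hits > 0 & hits + 20 <= nchar(seq))
}

# small noise-free simulation bundle used by several test files
small_sim <- function(n_genes = 50, n_tags = 2e4, seed = 11, ...) {
  cfg <- sim_config(n_genes = n_genes, n_tags_per_library = n_tags,
                    error_rate = 0, n_rate = 0, adapter_rate = 0,
                    seed = seed, ...)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(cfg)
  libs <- simulate_libraries(tx, truth, cfg)
  list(cfg = cfg, tx = tx, truth = truth, libs = libs)
}
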