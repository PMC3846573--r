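# Two-library differential expression for unreplicated tag counts.
#
# The core statistic is the Audic-Claverie conditional probability of
# observing y tags for a gene in a library of N2 clean tags given x
# tags in a library of N1 clean tags, under equal expression:
#
#   P(y|x) = (N2/N1)^y * (x+y)! / (x! y!) / (1 + N2/N1)^(x+y+1)
#
# i.e. y | x is negative binomial with size x+1 and success probability
# N1/(N1+N2). Everything is computed in log space via log-gamma so
# counts in the tens of thousands stay finite.

#' Audic-Claverie equal-expression probability P(y|x)
#'
#' @param x,y non-negative integer tag counts (CO and DS); vectorized
#' @param N1,N2 positive library totals (clean tags)
#' @param log return log probability
#' @return P(y|x) in (0, 1], or its log
#' @export
ac_probability <- function(x, y, N1, N2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  logr <- base::log(N2) - base::log(N1)
  log1pr <- log1p(N2 / N1)
  lp <- y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1pr
  if (log) lp else exp(lp)
}

# log P(y'|x) for y' = 0..ymax, by cumulative recurrence
# log P(y'|x) - log P(y'-1|x) = log((x+y')/y') + log(r/(1+r))
ac_log_pmf_upto <- function(x, ymax, N1, N2) {
  logr <- base::log(N2) - base::log(N1)
  log1pr <- log1p(N2 / N1)
  lp0 <- ac_probability(x, 0, N1, N2, log = TRUE)
  if (ymax == 0) return(lp0)
  yy <- seq_len(ymax)
  lp0 + c(0, cumsum(base::log((x + yy) / yy) + logr - log1pr))
}

# accuracy-preserving sum of exp(log-terms): summing in ascending order
# keeps the error at a few ulps without a scalar compensation loop
sum_exp_stable <- function(lp) {
  sum(sort(exp(lp)))
}

#' Two-sided Audic-Claverie p-value
#'
#' p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x))). Both tails are
#' computed by direct compensated summation of the log-space pmf (the
#' upper tail is summed upward from y until the geometric terms fall
#' below machine noise) so small p-values keep full relative precision
#' rather than being formed as 1 minus a near-1 lower tail.
#'
#' @inheritParams ac_probability
#' @return p-value(s) in (0, 1]
#' @export
two_sided_pvalue <- function(x, y, N1, N2) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i)
    ac_two_sided_one(x[i], y[i], N1[i], N2[i]), numeric(1))
}

ac_two_sided_one <- function(x, y, N1, N2) {
  if (x < 0 || y < 0) stop("counts must be non-negative")
  lpmf <- ac_log_pmf_upto(x, y, N1, N2)
  lower <- sum_exp_stable(lpmf)
  if (y == 0) {
    upper <- 1
  } else {
    lower_prev <- sum_exp_stable(lpmf[seq_len(y)]) # P(Y <= y-1)
    if (lower_prev <= 0.5) {
      # upper tail >= 0.5: the complement loses no relative precision
      upper <- 1 - lower_prev
    } else {
      # y is past the median, so the pmf decays from y on: sum directly
      upper <- ac_upper_tail(x, y, N1, N2)
    }
  }
  min(1, 2 * min(lower, upper))
}

# P(Y >= y | x) by Kahan-compensated upward summation from y
ac_upper_tail <- function(x, y, N1, N2) {
  logr <- base::log(N2) - base::log(N1)
  log1pr <- log1p(N2 / N1)
  lp <- ac_probability(x, y, N1, N2, log = TRUE)
  s <- exp(lp); comp <- 0
  yp <- y
  mean_y <- (x + 1) * exp(logr) # NB mean of Y given x
  repeat {
    yp <- yp + 1
    lp <- lp + base::log((x + yp) / yp) + logr - log1pr
    v <- exp(lp)
    t <- v - comp
    u <- s + t
    comp <- (u - s) - t
    s <- u
    # stop once past the mean and the running term is negligible (or has
    # underflowed entirely; s may be 0 when the whole tail is < 2^-1074)
    if (yp > mean_y && (v == 0 || v < s * 1e-18)) break
  }
  min(1, s)
}

#' TPM-scale log2 expression ratio (DS over CO)
#'
#' log2( max(y/N2 * 1e6, floor) / max(x/N1 * 1e6, floor) ). The floor
#' (TPM units) only guards zero counts in the ratio; it never enters the
#' test statistic.
#'
#' @inheritParams ac_probability
#' @param floor positive TPM floor for zero counts
#' @return log2 ratio(s)
#' @export
log2_ratio <- function(x, y, N1, N2, floor = 0.001) {
  if (any(floor <= 0)) stop("floor must be positive")
  log2(pmax(y / N2 * 1e6, floor) / pmax(x / N1 * 1e6, floor))
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg step-up (default) or Benjamini-Yekutieli:
#' adj p_(i) = min_{j >= i} min(1, m/j * p_(j)), with the BY variant
#' multiplying by the harmonic number H_m.
#'
#' @param p p-values in [0, 1]
#' @param method "BH" or "BY"
#' @return adjusted values, same order as input
#' @export
fdr_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  mult <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p, decreasing = TRUE)
  ranks <- m:1
  adj <- pmin(1, cummin(mult * m / ranks * p[o]))
  adj[order(o)]
}

#' Two-library differential expression test
#'
#' Runs the Audic-Claverie two-sided test per gene, BH-adjusts the
#' p-values, computes TPM and the floored log2 ratio, and classifies
#' calls. Genes with x = y = 0 (undetected in both libraries) are
#' excluded from testing.
#'
#' @param counts data.frame with columns gene_id, x (CO count), y (DS
#'   count)
#' @param N1,N2 clean-tag totals of the CO and DS libraries
#' @param fdr_cut,lfc_cut call thresholds (default FDR <= 0.001 and
#'   |log2 ratio| >= 1)
#' @param tpm_floor TPM floor for the ratio
#' @param method FDR method, "BH" or "BY"
#' @return data.frame (class `de_result`): gene_id, x, y, tpm_co,
#'   tpm_ds, log2_ratio, p, fdr, call in \{up, down, none\}
#' @export
de_test <- function(counts, N1, N2, fdr_cut = 0.001, lfc_cut = 1,
                    tpm_floor = 0.001, method = "BH") {
  stopifnot(all(c("gene_id", "x", "y") %in% names(counts)))
  counts <- counts[counts$x + counts$y > 0, , drop = FALSE]
  x <- counts$x; y <- counts$y
  res <- data.frame(
    gene_id = counts$gene_id,
    x = x, y = y,
    tpm_co = x / N1 * 1e6,
    tpm_ds = y / N2 * 1e6,
    log2_ratio = log2_ratio(x, y, N1, N2, tpm_floor),
    p = two_sided_pvalue(x, y, N1, N2),
    stringsAsFactors = FALSE
  )
  res$fdr <- fdr_adjust(res$p, method)
  res <- classify_degs(res, fdr_cut, lfc_cut)$results
  attr(res, "N1") <- N1
  attr(res, "N2") <- N2
  class(res) <- c("de_result", "data.frame")
  res
}

#' Classify differentially expressed genes
#'
#' up: fdr <= fdr_cut and log2_ratio >= lfc_cut; down: fdr <= fdr_cut
#' and log2_ratio <= -lfc_cut; none otherwise. The summary reports call
#' counts and the shares of tested genes whose expression difference is
#' within / beyond 5-fold.
#'
#' @param results data.frame with fdr and log2_ratio columns
#' @param fdr_cut,lfc_cut thresholds
#' @return list: `results` (with a `call` column) and `summary`
#'   (n_up, n_down, n_tested, frac_within_5fold, frac_up_gt5,
#'   frac_down_gt5)
#' @export
classify_degs <- function(results, fdr_cut = 0.001, lfc_cut = 1) {
  call <- rep("none", nrow(results))
  sig <- results$fdr <= fdr_cut
  call[sig & results$log2_ratio >= lfc_cut] <- "up"
  call[sig & results$log2_ratio <= -lfc_cut] <- "down"
  results$call <- call
  l5 <- log2(5)
  n <- nrow(results)
  summary <- list(
    n_up = sum(call == "up"),
    n_down = sum(call == "down"),
    n_tested = n,
    frac_within_5fold = if (n) mean(abs(results$log2_ratio) <= l5) else NA_real_,
    frac_up_gt5 = if (n) mean(results$log2_ratio > l5) else NA_real_,
    frac_down_gt5 = if (n) mean(results$log2_ratio < -l5) else NA_real_
  )
  list(results = results, summary = summary)
}
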