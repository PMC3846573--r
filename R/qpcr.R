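# qPCR validation: reference-gene stability and relative quantification.
#
# Ct tables hold one row per (sample, condition, gene, replicate). The
# reference gene (e.g. actin) is checked for stability between
# conditions with a Welch t-test on its Ct values; target fold changes
# are computed by the Livak 2^-ddCt method (100% amplification
# efficiency assumed), with an efficiency-corrected (Pfaffl-style)
# variant available through the efficiency arguments.

#' Read a Ct table from CSV
#'
#' Expected columns: sample_id, condition (CO/DS), gene_id, replicate,
#' ct.
#' @param path CSV file
#' @return validated Ct data.frame
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct(ct)
}

validate_ct <- function(ct) {
  need <- c("condition", "gene_id", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!ct$condition %in% c("CO", "DS")))
    stop("condition must be CO or DS")
  if (any(ct$ct <= 0)) stop("Ct values must be positive cycle counts")
  ct
}

#' Reference-gene stability t-test
#'
#' Two-sample two-sided Welch t-test on the reference gene's Ct values
#' between conditions. P > 0.05 supports using the gene as endogenous
#' control. Degenerate zero-variance data are guarded with a small
#' variance epsilon instead of erroring.
#'
#' @param ct Ct data.frame (see [read_ct_csv()])
#' @param reference reference gene id
#' @param alpha stability threshold on the p-value
#' @return list: t, p, df, stable (p > alpha)
#' @export
reference_stability <- function(ct, reference, alpha = 0.05) {
  ct <- validate_ct(ct)
  v <- ct[ct$gene_id == reference, ]
  co <- v$ct[v$condition == "CO"]
  ds <- v$ct[v$condition == "DS"]
  if (length(co) < 2 || length(ds) < 2)
    stop("need >= 2 reference Ct values per condition")
  if (stats::var(co) < 1e-12 && stats::var(ds) < 1e-12) {
    eps <- 1e-12
    se <- sqrt(eps / length(co) + eps / length(ds))
    tt <- (mean(co) - mean(ds)) / se
    p <- if (abs(mean(co) - mean(ds)) < 1e-12) 1 else 0
    return(list(t = tt, p = p, df = length(co) + length(ds) - 2,
                stable = p > alpha))
  }
  ht <- stats::t.test(co, ds, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), stable = ht$p.value > alpha)
}

#' Relative fold change by 2^-ddCt
#'
#' Per condition, dCt = mean Ct(target) - mean Ct(reference); ddCt =
#' dCt(DS) - dCt(CO); fold = 2^-ddCt. Replicate SDs propagate in
#' quadrature through dCt and ddCt, and the fold range is
#' 2^-(ddCt +/- SD). With `e_target`/`e_reference` different from 2 the
#' efficiency-corrected ratio
#' `e_target^-(dCt_ds_t - dCt_co_t) / e_reference^-(...)` is used.
#'
#' @param ct Ct data.frame
#' @param target target gene id
#' @param reference reference (endogenous control) gene id
#' @param e_target,e_reference amplification efficiencies as per-cycle
#'   amplification factors (2 = 100\% efficiency, Livak)
#' @return list: fold, lo, hi (fold range from +/- SD), ddct, sd_ddct,
#'   direction ("up", "down" or "none")
#' @export
qpcr_fold_change <- function(ct, target, reference,
                             e_target = 2, e_reference = 2) {
  ct <- validate_ct(ct)
  grab <- function(gene, cond) {
    v <- ct$ct[ct$gene_id == gene & ct$condition == cond]
    if (!length(v)) stop("no Ct values for ", gene, " in ", cond)
    v
  }
  stats_of <- function(v) c(m = mean(v), s = stats::sd(v))
  co_t <- stats_of(grab(target, "CO")); co_r <- stats_of(grab(reference, "CO"))
  ds_t <- stats_of(grab(target, "DS")); ds_r <- stats_of(grab(reference, "DS"))
  sd0 <- function(s) if (is.na(s)) 0 else s
  if (e_target == 2 && e_reference == 2) {
    dct_co <- co_t["m"] - co_r["m"]
    dct_ds <- ds_t["m"] - ds_r["m"]
    ddct <- unname(dct_ds - dct_co)
    fold <- 2^(-ddct)
  } else {
    # Pfaffl ratio: efficiencies applied per gene to CO-vs-DS Ct shifts
    fold <- (e_target^(co_t["m"] - ds_t["m"])) /
      (e_reference^(co_r["m"] - ds_r["m"]))
    fold <- unname(fold)
    ddct <- -log2(fold)
  }
  sd_ddct <- sqrt(sd0(co_t["s"])^2 + sd0(co_r["s"])^2 +
                  sd0(ds_t["s"])^2 + sd0(ds_r["s"])^2)
  sd_ddct <- unname(sd_ddct)
  list(fold = fold,
       lo = 2^(-(ddct + sd_ddct)),
       hi = 2^(-(ddct - sd_ddct)),
       ddct = ddct,
       sd_ddct = sd_ddct,
       direction = if (fold > 1) "up" else if (fold < 1) "down" else "none")
}

#' Fold-change table for a panel of validation genes
#'
#' @param ct Ct data.frame
#' @param reference reference gene id
#' @param targets target genes; default every non-reference gene
#' @return data.frame: gene_id, fold, lo, hi, direction
#' @export
qpcr_table <- function(ct, reference, targets = NULL) {
  ct <- validate_ct(ct)
  if (is.null(targets))
    targets <- setdiff(unique(ct$gene_id), reference)
  rows <- lapply(targets, function(g) {
    fc <- qpcr_fold_change(ct, g, reference)
    data.frame(gene_id = g, fold = fc$fold, lo = fc$lo, hi = fc$hi,
               direction = fc$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
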