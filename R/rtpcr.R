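#' Delta-delta-Ct relative quantification
#'
#' Classic comparative-Ct quantification of a target gene normalized to a
#' reference gene (e.g. the principal sigma factor *sigA*) and expressed
#' relative to a calibrator sample:
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt_test - dCt_calibrator`, relative expression
#' `= E^(-ddCt)` with amplification efficiency `E = 2` by default (the
#' standard assumption of perfect doubling per cycle). The calibrator
#' sample returns 1 by construction. Replicate Ct measurements for a
#' (sample, gene) pair are averaged before the calculation.
#'
#' @param ct_table Tibble `sample`, `gene`, `ct` (one row per replicate
#'   measurement).
#' @param target_gene,reference_gene Gene names present in `ct_table`.
#' @param calibrator_sample Sample whose expression is set to 1.
#' @param efficiency Amplification efficiency (fold amplification per
#'   cycle). Default 2.
#' @return Tibble `sample`, `d_ct`, `dd_ct`, `rel_expression` with one row
#'   per sample in `ct_table`.
#' @export
ddct <- function(ct_table, target_gene, reference_gene, calibrator_sample,
                 efficiency = 2) {
  if (!all(c("sample", "gene", "ct") %in% names(ct_table))) {
    eq_abort("ct_table must have columns sample, gene, ct",
             "empaiq_invalid_input")
  }
  samples <- unique(ct_table$sample)
  if (!calibrator_sample %in% samples) {
    eq_abort(sprintf("calibrator sample '%s' not in ct_table",
                     calibrator_sample), "empaiq_missing_record")
  }
  mean_ct <- function(smp, gene) {
    ct <- ct_table$ct[ct_table$sample == smp & ct_table$gene == gene]
    if (!length(ct) || any(is.na(ct))) {
      eq_abort(sprintf("missing Ct for sample '%s', gene '%s'", smp, gene),
               "empaiq_missing_record")
    }
    mean(ct)
  }
  d_ct <- vapply(samples, function(smp) {
    mean_ct(smp, target_gene) - mean_ct(smp, reference_gene)
  }, numeric(1))
  dd_ct <- d_ct - d_ct[samples == calibrator_sample]
  tibble::tibble(sample = samples, d_ct = unname(d_ct),
                 dd_ct = unname(dd_ct),
                 rel_expression = efficiency^(-unname(dd_ct)))
}

#' Fold-change table for several target genes
#'
#' Convenience wrapper running [ddct()] for each target gene against one
#' reference gene and calibrator.
#'
#' @inheritParams ddct
#' @param target_genes Character vector of target genes.
#' @return Tibble `gene`, `sample`, `rel_expression`.
#' @export
ddct_table <- function(ct_table, target_genes, reference_gene,
                       calibrator_sample, efficiency = 2) {
  dplyr::bind_rows(lapply(target_genes, function(g) {
    res <- ddct(ct_table, g, reference_gene, calibrator_sample,
                efficiency = efficiency)
    tibble::tibble(gene = g, sample = res$sample,
                   rel_expression = res$rel_expression)
  }))
}

#' Summarize replicate fold-change determinations
#'
#' Mean and error bar over independent replicate determinations of a
#' relative expression value. The error bar is the standard error of the
#' mean by default (switch to `"sd"` for the standard deviation).
#'
#' @param folds Numeric vector of replicate fold values (length >= 2).
#' @param error Either `"sem"` (default) or `"sd"`.
#' @return Named list `mean`, `error`, `n`.
#' @export
replicate_summary <- function(folds, error = c("sem", "sd")) {
  error <- match.arg(error)
  if (length(folds) < 2L || any(is.na(folds))) {
    eq_abort("need at least 2 replicate determinations",
             "empaiq_invalid_input")
  }
  s <- stats::sd(folds)
  list(mean = mean(folds),
       error = if (error == "sem") s / sqrt(length(folds)) else s,
       n = length(folds))
}
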