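#' Partition two identification sets into shared and exclusive proteins
#'
#' @param ids_a,ids_b Character vectors of accessions identified in each
#'   strain (duplicates ignored).
#' @return A list of class `set_partition`: `shared`, `exclusive_a`,
#'   `exclusive_b` (sorted accession vectors) and `sizes` (named integer
#'   vector `n_a`, `n_b`, `shared`, `exclusive_a`, `exclusive_b`, `union`).
#' @examples
#' partition_sets(c("p1", "p2", "p3"), c("p2", "p3", "p4"))
#' @export
partition_sets <- function(ids_a, ids_b) {
  a <- unique(as.character(ids_a))
  b <- unique(as.character(ids_b))
  shared <- sort(intersect(a, b))
  ex_a <- sort(setdiff(a, b))
  ex_b <- sort(setdiff(b, a))
  structure(
    list(shared = shared, exclusive_a = ex_a, exclusive_b = ex_b,
         sizes = c(n_a = length(a), n_b = length(b),
                   shared = length(shared),
                   exclusive_a = length(ex_a), exclusive_b = length(ex_b),
                   union = length(union(a, b)))),
    class = "set_partition"
  )
}

#' @export
print.set_partition <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(
    "Protein set partition: %d vs %d identified, %d shared, %d/%d exclusive, union %d\n",
    s["n_a"], s["n_b"], s["shared"], s["exclusive_a"], s["exclusive_b"],
    s["union"]))
  invisible(x)
}

# interval ratio with the non-positive-denominator convention:
# denominator <= 0 with positive numerator -> +Inf; numerator and
# denominator both <= 0 -> NA (undefined, classifier treats as constant)
interval_ratio <- function(num, den) {
  if (den > 0) return(num / den)
  if (num > 0) return(Inf)
  NA_real_
}

# Welch (default) or pooled t-test p-value that tolerates degenerate
# (essentially constant) data, where t.test() errors
safe_t_p <- function(x, y, var_equal = FALSE) {
  eps <- 1e-12
  if (sd(x) < eps && sd(y) < eps) {
    return(if (abs(mean(x) - mean(y)) < eps) 1 else 0)
  }
  tryCatch(
    stats::t.test(x, y, var.equal = var_equal)$p.value,
    error = function(e) if (abs(mean(x) - mean(y)) < eps) 1 else 0
  )
}

#' Classify one shared protein as increased, decreased, or constant
#'
#' Applies the interval-ratio rules between the test strain (PR2) and the
#' reference strain, gated by a two-sample t-test on the per-run emPAI
#' values: *increased* when `p < alpha` and
#' `PR2(MEP - MSD) / REF(MEP + MSD) >= up`; *decreased* when `p < alpha`
#' and `PR2(MEP + MSD) / REF(MEP - MSD) <= down`; otherwise *constant*
#' (overlapping intervals fail both ratio gates). The default thresholds
#' 1.5 and 0.67 are kept exactly as published; note 0.67 is not exactly
#' 1/1.5, so the rule is not perfectly symmetric under a strain swap.
#'
#' Because MEP - MSD can be non-positive, a ratio with a non-positive
#' denominator is treated as +Inf when the numerator is positive and as
#' undefined (constant) when both are non-positive.
#'
#' @param pr2_values,ref_values Per-run emPAI values for the test and
#'   reference strain (each length >= 2).
#' @param alpha Significance gate for the t-test. Default 0.05.
#' @param up Minimum up-ratio for an increased call. Default 1.5.
#' @param down Maximum down-ratio for a decreased call. Default 0.67.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param sample_sd Passed to [empai_summary()].
#' @return Named list: `ratio_up`, `ratio_down`, `p_value`, `call` (one of
#'   `"increased"`, `"decreased"`, `"constant"`).
#' @export
classify_protein <- function(pr2_values, ref_values, alpha = 0.05,
                             up = 1.5, down = 0.67, var_equal = FALSE,
                             sample_sd = FALSE) {
  q2 <- empai_summary(pr2_values, sample_sd = sample_sd)
  q1 <- empai_summary(ref_values, sample_sd = sample_sd)
  ratio_up <- interval_ratio(q2$lower, q1$upper)
  ratio_down <- interval_ratio(q2$upper, q1$lower)
  p <- safe_t_p(pr2_values, ref_values, var_equal = var_equal)
  call <- "constant"
  if (!is.na(p) && p < alpha) {
    if (!is.na(ratio_up) && ratio_up >= up) {
      call <- "increased"
    } else if (!is.na(ratio_down) && ratio_down <= down) {
      call <- "decreased"
    }
  }
  list(ratio_up = ratio_up, ratio_down = ratio_down, p_value = p,
       call = call)
}

#' Differential calls for all shared proteins
#'
#' Runs [classify_protein()] on every shared protein of a partition and
#' tallies increased/decreased/constant calls. Strain-exclusive proteins
#' are never classified; they are reported separately by the pipeline.
#'
#' @param quant_pr2,quant_ref Per-strain quantification tibbles from
#'   [quantify_strains()] (one strain each).
#' @param partition A [partition_sets()] result; defaults to the partition
#'   of the two tibbles' accessions.
#' @param alpha,up,down,var_equal Passed to [classify_protein()].
#' @param p_adjust Optional multiple-testing correction method for the gate
#'   (any [stats::p.adjust()] method); `"none"` (default) matches the raw
#'   p < alpha rule of the original analysis.
#' @return A list of class `differential_result`: `calls` (tibble with
#'   `accession`, MEP/MSD for both strains, `ratio_up`, `ratio_down`,
#'   `p_value`, `call`) and `summary` (list with `shared`, `increased`,
#'   `decreased`, `constant`, `pct_changed`, `pct_constant`, percentages
#'   rounded to the nearest integer).
#' @export
call_table <- function(quant_pr2, quant_ref, partition = NULL,
                       alpha = 0.05, up = 1.5, down = 0.67,
                       var_equal = FALSE, p_adjust = "none") {
  if (is.null(partition)) {
    partition <- partition_sets(quant_ref$accession, quant_pr2$accession)
  }
  shared <- partition$shared
  missing <- c(setdiff(shared, quant_pr2$accession),
               setdiff(shared, quant_ref$accession))
  if (length(missing)) {
    eq_abort(paste0("missing quantification record for shared accession(s): ",
                    paste(head(unique(missing), 5), collapse = ", ")),
             "empaiq_missing_record")
  }
  if (!length(shared)) {
    calls <- tibble::tibble(
      accession = character(), mep_pr2 = numeric(), msd_pr2 = numeric(),
      mep_ref = numeric(), msd_ref = numeric(), ratio_up = numeric(),
      ratio_down = numeric(), p_value = numeric(), call = character())
    return(structure(
      list(calls = calls,
           summary = list(shared = 0L, increased = 0L, decreased = 0L,
                          constant = 0L, pct_changed = 0, pct_constant = 0)),
      class = "differential_result"))
  }

  i2 <- match(shared, quant_pr2$accession)
  i1 <- match(shared, quant_ref$accession)
  res <- lapply(seq_along(shared), function(k) {
    classify_protein(quant_pr2$run_values[[i2[k]]],
                     quant_ref$run_values[[i1[k]]],
                     alpha = alpha, up = up, down = down,
                     var_equal = var_equal)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p_value")
  if (!identical(p_adjust, "none")) {
    # re-gate on adjusted p-values, ratio gates unchanged
    p_adj <- stats::p.adjust(p_raw, method = p_adjust)
    for (k in seq_along(res)) {
      if (res[[k]]$call != "constant" && p_adj[k] >= alpha) {
        res[[k]]$call <- "constant"
      }
      res[[k]]$p_value <- p_adj[k]
    }
  }
  calls <- tibble::tibble(
    accession = shared,
    mep_pr2 = quant_pr2$mep[i2], msd_pr2 = quant_pr2$msd[i2],
    mep_ref = quant_ref$mep[i1], msd_ref = quant_ref$msd[i1],
    ratio_up = vapply(res, `[[`, numeric(1), "ratio_up"),
    ratio_down = vapply(res, `[[`, numeric(1), "ratio_down"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    call = vapply(res, `[[`, character(1), "call")
  )
  n_i <- sum(calls$call == "increased")
  n_d <- sum(calls$call == "decreased")
  n_c <- sum(calls$call == "constant")
  summary <- list(
    shared = length(shared), increased = n_i, decreased = n_d,
    constant = n_c,
    pct_changed = round(100 * (n_i + n_d) / length(shared)),
    pct_constant = round(100 * n_c / length(shared))
  )
  structure(list(calls = calls, summary = summary),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Differential calls over %d shared proteins: %d increased, %d decreased, %d constant (%d%% changed)\n",
    s$shared, s$increased, s$decreased, s$constant, s$pct_changed))
  invisible(x)
}
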