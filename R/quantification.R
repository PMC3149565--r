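#' Exponentially modified protein abundance index (emPAI)
#'
#' Spectral-count abundance estimate for one protein in one run:
#' `empai = 10^(SC / OP) - 1`, where SC is the protein's MS/MS spectral
#' count in the run and OP its number of observable tryptic peptides.
#' Dividing SC by OP corrects the count for protein size before the
#' exponential modification. Note the source study elides the formula line
#' itself; this is the standard emPAI definition from the spectral-counting
#' literature it builds on.
#'
#' @param sc Non-negative spectral count(s).
#' @param op Positive observable-peptide count(s) (recycled).
#' @return Dimensionless abundance, zero iff `sc == 0`.
#' @examples
#' empai(0, 5)  # 0
#' empai(5, 5)  # 9
#' @export
empai <- function(sc, op) {
  if (any(is.na(sc)) || any(sc < 0)) {
    eq_abort("spectral counts must be non-negative", "empaiq_invalid_input")
  }
  if (any(is.na(op)) || any(op < 1)) {
    eq_abort("protein has no observable peptides (op < 1): emPAI undefined",
             "empaiq_undefined_abundance")
  }
  10^(sc / op) - 1
}

#' Mean emPAI (MEP) and mean square deviation (MSD)
#'
#' Summarizes a protein's per-run emPAI values across the replicate shotgun
#' runs of one strain. MEP is the arithmetic mean; MSD is the
#' root-mean-square deviation about MEP (population form, dividing by n;
#' set `sample_sd = TRUE` for the n-1 sample standard deviation). The
#' expression interval used by the differential classifier is
#' `[MEP - MSD, MEP + MSD]`.
#'
#' @param values Numeric vector of per-run emPAI values (length >= 2).
#' @param sample_sd Use the n-1 denominator instead of n. Default `FALSE`.
#' @return Named list with `mep`, `msd`, `lower`, `upper`.
#' @examples
#' empai_summary(c(0, 2)) # mep 1, msd 1
#' @export
empai_summary <- function(values, sample_sd = FALSE) {
  if (length(values) < 2L || any(is.na(values))) {
    eq_abort("need at least 2 non-missing per-run values to summarize",
             "empaiq_invalid_input")
  }
  mep <- mean(values)
  denom <- if (sample_sd) length(values) - 1L else length(values)
  msd <- sqrt(sum((values - mep)^2) / denom)
  list(mep = mep, msd = msd, lower = mep - msd, upper = mep + msd)
}

#' Per-strain emPAI quantification
#'
#' Joins the spectral-count matrix with the observable-peptide table and
#' computes, for every protein detected in each strain, the per-run emPAI
#' values and their MEP/MSD interval over that strain's runs. A protein is
#' "detected" in a strain if it has a nonzero spectral count in at least one
#' of the strain's runs; runs where a detected protein was not observed
#' contribute SC = 0 (hence emPAI = 0), not a missing value.
#'
#' @param counts Tibble `accession`, `run_id`, `spectral_count` (long form;
#'   absent combinations are treated as zero).
#' @param design Tibble `run_id`, `strain` (plus any other run metadata).
#' @param op_table Tibble `accession`, `op` from [observable_peptides()].
#' @param sample_sd Passed to [empai_summary()].
#' @return Tibble with one row per (accession, strain) in which the protein
#'   was detected: `accession`, `strain`, `mep`, `msd`, `lower`, `upper`,
#'   `n_runs`, and `run_values` (list column of per-run emPAI, ordered by
#'   `run_id`).
#' @export
quantify_strains <- function(counts, design, op_table, sample_sd = FALSE) {
  required <- c("accession", "run_id", "spectral_count")
  if (!all(required %in% names(counts))) {
    eq_abort("counts must have columns accession, run_id, spectral_count",
             "empaiq_invalid_input")
  }
  if (!all(c("run_id", "strain") %in% names(design))) {
    eq_abort("design must have columns run_id, strain",
             "empaiq_invalid_input")
  }
  missing_op <- setdiff(unique(counts$accession), op_table$accession)
  if (length(missing_op)) {
    eq_abort(paste0("no observable-peptide entry for: ",
                    paste(head(missing_op, 5), collapse = ", ")),
             "empaiq_undefined_abundance")
  }

  out <- vector("list", 0L)
  for (st in unique(design$strain)) {
    runs <- sort(design$run_id[design$strain == st])
    sub <- counts[counts$run_id %in% runs, , drop = FALSE]
    detected <- sort(unique(sub$accession[sub$spectral_count > 0]))
    if (!length(detected)) next
    # dense accession x run count matrix with zeros for absent pairs
    mat <- matrix(0, nrow = length(detected), ncol = length(runs),
                  dimnames = list(detected, runs))
    sub <- sub[sub$accession %in% detected, , drop = FALSE]
    mat[cbind(match(sub$accession, detected), match(sub$run_id, runs))] <-
      sub$spectral_count
    op <- op_table$op[match(detected, op_table$accession)]
    emp <- empai(mat, rep(op, times = length(runs)))
    dim(emp) <- dim(mat)
    summaries <- lapply(seq_along(detected), function(i) {
      empai_summary(emp[i, ], sample_sd = sample_sd)
    })
    out[[length(out) + 1L]] <- tibble::tibble(
      accession = detected,
      strain = st,
      mep = vapply(summaries, `[[`, numeric(1), "mep"),
      msd = vapply(summaries, `[[`, numeric(1), "msd"),
      lower = vapply(summaries, `[[`, numeric(1), "lower"),
      upper = vapply(summaries, `[[`, numeric(1), "upper"),
      n_runs = length(runs),
      run_values = lapply(seq_along(detected), function(i) emp[i, ])
    )
  }
  if (!length(out)) {
    return(tibble::tibble(accession = character(), strain = character(),
                          mep = numeric(), msd = numeric(),
                          lower = numeric(), upper = numeric(),
                          n_runs = integer(), run_values = list()))
  }
  dplyr::bind_rows(out)
}
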