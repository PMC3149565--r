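#' The ten default functional categories
#'
#' Biological-process categories used to profile the two proteomes. Proteins
#' with no mapping fall into `"no description"`.
#'
#' @return Character vector of the 10 category names.
#' @export
functional_categories <- function() {
  c("biosynthetic process", "catabolic process", "oxidation reduction",
    "transcription", "translation", "transport", "TCA cycle",
    "proteolysis", "glycolysis", "other")
}

UNCLASSIFIED <- "no description"

#' Map accessions to functional categories
#'
#' @param accessions Character vector of accessions.
#' @param go_map Tibble `accession`, `category` (a flat mapping table, e.g.
#'   exported from a GO annotation); accessions absent from the map get
#'   `"no description"`.
#' @return Character vector of categories, same length as `accessions`.
#' @export
assign_category <- function(accessions, go_map) {
  if (!all(c("accession", "category") %in% names(go_map))) {
    eq_abort("go_map must have columns accession, category",
             "empaiq_invalid_input")
  }
  cat <- go_map$category[match(accessions, go_map$accession)]
  cat[is.na(cat)] <- UNCLASSIFIED
  cat
}

#' Functional-category profile of a protein set
#'
#' Counts and percentages over the functional categories for one strain's
#' identified proteins. Percentages are stored at full precision; round for
#' reporting.
#'
#' @param accessions Nonempty character vector of identified accessions.
#' @param go_map Mapping table, see [assign_category()].
#' @param categories Category universe; defaults to the 10 standard
#'   categories plus `"no description"`.
#' @return Tibble `category`, `count`, `percentage` (of `length(accessions)`),
#'   with an `n_total` attribute.
#' @export
category_profile <- function(accessions, go_map,
                             categories = c(functional_categories(),
                                            UNCLASSIFIED)) {
  if (!length(accessions)) {
    eq_abort("cannot profile an empty protein set", "empaiq_invalid_input")
  }
  assigned <- assign_category(accessions, go_map)
  extra <- setdiff(unique(assigned), categories)
  counts <- table(factor(assigned, levels = c(categories, extra)))
  out <- tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    percentage = 100 * as.integer(counts) / length(accessions)
  )
  attr(out, "n_total") <- length(accessions)
  out
}

#' Between-strain category fold change
#'
#' Per-category ratio of percentage in the test-strain profile over
#' percentage in the reference profile (values > 1 mean the category is
#' enriched in the test strain). A zero reference percentage makes the
#' ratio undefined (`NA`), not infinite.
#'
#' @param profile_test,profile_ref [category_profile()] tibbles over the
#'   same category set.
#' @return Tibble `category`, `pct_test`, `pct_ref`, `fold_change`.
#' @export
category_fold_change <- function(profile_test, profile_ref) {
  if (!setequal(profile_test$category, profile_ref$category)) {
    eq_abort("profiles must cover the same category set",
             "empaiq_invalid_input")
  }
  ref <- profile_ref$percentage[match(profile_test$category,
                                      profile_ref$category)]
  fc <- ifelse(ref > 0, profile_test$percentage / ref, NA_real_)
  tibble::tibble(category = profile_test$category,
                 pct_test = profile_test$percentage,
                 pct_ref = ref,
                 fold_change = fc)
}

# EMBOSS pK scale: termini plus the seven ionizable side chains
PK_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# net charge of a protein at a given pH (Henderson-Hasselbalch);
# strictly decreasing in pH
protein_charge <- function(counts, pH, pk = PK_EMBOSS) {
  pos <- 1 / (1 + 10^(pH - pk["Nterm"])) +
    counts["K"] / (1 + 10^(pH - pk["K"])) +
    counts["R"] / (1 + 10^(pH - pk["R"])) +
    counts["H"] / (1 + 10^(pH - pk["H"]))
  neg <- 1 / (1 + 10^(pk["Cterm"] - pH)) +
    counts["D"] / (1 + 10^(pk["D"] - pH)) +
    counts["E"] / (1 + 10^(pk["E"] - pH)) +
    counts["C"] / (1 + 10^(pk["C"] - pH)) +
    counts["Y"] / (1 + 10^(pk["Y"] - pH))
  unname(pos - neg)
}

#' Theoretical isoelectric point
#'
#' pH at which the net protein charge (termini plus D, E, C, Y, H, K, R
#' side chains under Henderson-Hasselbalch) is zero, found by bisection.
#' The default pK set is the EMBOSS scale; other scales shift pI by roughly
#' 0.1-0.3 pH units, so the scale in use is part of any reported result.
#'
#' @param sequence Protein sequence (canonical amino acids).
#' @param pk Named numeric vector of pK values with names `Nterm`, `Cterm`,
#'   `C`, `D`, `E`, `H`, `K`, `R`, `Y`.
#' @param tol Bisection tolerance on pH. Default `1e-6`.
#' @return pI in pH units.
#' @examples
#' protein_pi("KKKK") > protein_pi("DDDD")
#' @export
protein_pi <- function(sequence, pk = PK_EMBOSS, tol = 1e-6) {
  s <- check_sequence(sequence, "protein sequence")
  chars <- strsplit(s, "")[[1]]
  counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(counts, mid, pk) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Histogram of values over explicit bin edges
#'
#' Bins are half-open `[low, high)` except the last, which is closed, so a
#' value equal to the final edge is counted. Values outside the outermost
#' edges are excluded from counts and reported via the `n_outside`
#' attribute; percentages are relative to the number of input values.
#'
#' @param values Numeric vector.
#' @param edges Sorted numeric vector of bin edges (length >= 2).
#' @return Tibble `bin_low`, `bin_high`, `count`, `percentage` with
#'   attribute `n_outside`.
#' @export
distribution_bins <- function(values, edges) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    eq_abort("edges must be strictly increasing with length >= 2",
             "empaiq_invalid_input")
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= length(edges) - 1L
  counts <- tabulate(idx[inside], nbins = length(edges) - 1L)
  out <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    count = counts,
    percentage = if (length(values)) 100 * counts / length(values) else
      rep(0, length(counts))
  )
  attr(out, "n_outside") <- sum(!inside)
  out
}
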