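#' Digestion and observable-peptide parameters
#'
#' Parameter set for in silico tryptic digestion and observable-peptide (OP)
#' counting. The default mass window of 600--3500 Da corresponds to the scan
#' range of an LTQ-class ion-trap instrument: theoretical peptides outside it
#' are not observable and are eliminated before counting.
#'
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   allowed in a product (non-negative integer). The observable-peptide
#'   count uses 0 by default: fully cleaved products only.
#' @param mass_window Numeric pair `c(low, high)` in Da; peptides with
#'   `low <= mass <= high` (inclusive) count as observable.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @param proline_rule Suppress cleavage when the residue after K/R is
#'   proline (standard trypsin specificity). Default `TRUE`.
#' @param count_unique_only Count each distinct peptide sequence once when
#'   tallying OP. Default `TRUE`.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 0L,
                          mass_window = c(600, 3500),
                          mass_type = c("monoisotopic", "average"),
                          proline_rule = TRUE,
                          count_unique_only = TRUE) {
  mass_type <- match.arg(mass_type)
  if (length(missed_cleavages) != 1L || is.na(missed_cleavages) ||
      missed_cleavages < 0 || missed_cleavages != floor(missed_cleavages)) {
    eq_abort("missed_cleavages must be a single non-negative integer",
             "empaiq_invalid_params")
  }
  if (length(mass_window) != 2L || any(is.na(mass_window)) ||
      mass_window[1] >= mass_window[2]) {
    eq_abort("mass_window must be c(low, high) with low < high",
             "empaiq_invalid_params")
  }
  structure(
    list(missed_cleavages = as.integer(missed_cleavages),
         mass_window = as.numeric(mass_window),
         mass_type = mass_type,
         proline_rule = isTRUE(proline_rule),
         count_unique_only = isTRUE(count_unique_only)),
    class = "digest_params"
  )
}

# 0-based positions after which trypsin cleaves: after K or R, optionally
# not before P; never after the final residue
cleavage_sites <- function(chars, proline_rule = TRUE) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  if (proline_rule && length(idx)) {
    idx <- idx[chars[idx + 1L] != "P"]
  }
  idx
}

#' In silico tryptic digestion
#'
#' Cleaves a protein C-terminal to lysine and arginine (optionally not
#' before proline) and enumerates all products with at most
#' `missed_cleavages` internal missed cleavage sites. At
#' `missed_cleavages = 0` the products are the fully cleaved fragments and
#' concatenate back to the input sequence.
#'
#' @param sequence Protein sequence (canonical amino acids).
#' @param params A [digest_params()] object.
#' @return Tibble with one row per product: `peptide`, `mass` (Da, per
#'   `params$mass_type`), `start`/`end` (0-based half-open coordinates in
#'   the parent), and `n_missed` (internal missed cleavage sites spanned).
#' @examples
#' tryptic_digest("AKRPCK")           # proline blocks cleavage after R
#' tryptic_digest("AKCK", digest_params(missed_cleavages = 1))
#' @export
tryptic_digest <- function(sequence, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  s <- check_sequence(sequence, "protein sequence")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  sites <- cleavage_sites(chars, params$proline_rule)
  bounds <- c(0L, sites, n)            # fragment boundaries, 0-based
  nfrag <- length(bounds) - 1L
  m <- params$missed_cleavages

  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + m)
    for (j in i:jmax) {
      starts <- c(starts, bounds[i])
      ends <- c(ends, bounds[j + 1L])
      missed <- c(missed, j - i)
    }
  }
  peps <- substring(s, starts + 1L, ends)
  masses <- vapply(peps, peptide_mass, numeric(1),
                   mass_type = params$mass_type, USE.NAMES = FALSE)
  tibble::tibble(peptide = peps, mass = masses,
                 start = starts, end = ends, n_missed = missed)
}

#' Count observable peptides (OP)
#'
#' Number of digestion products whose mass lies inside the instrument scan
#' window (inclusive bounds). With `count_unique_only` (the default) each
#' distinct peptide sequence counts once.
#'
#' @param peptides Tibble from [tryptic_digest()] (columns `peptide`,
#'   `mass`).
#' @param params A [digest_params()] object supplying the mass window.
#' @return Non-negative integer OP count.
#' @export
count_observable <- function(peptides, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  w <- params$mass_window
  keep <- peptides$mass >= w[1] & peptides$mass <= w[2]
  seqs <- peptides$peptide[keep]
  if (params$count_unique_only) seqs <- unique(seqs)
  length(seqs)
}

#' Observable-peptide table for a protein set
#'
#' Digests every protein and tallies its observable peptides under the given
#' parameters. This is the denominator table for emPAI.
#'
#' @param proteins Named character vector of sequences, a
#'   `Biostrings::AAStringSet`, or a path to a FASTA file.
#' @param params A [digest_params()] object.
#' @return Tibble with columns `accession`, `length`, `op`.
#' @export
observable_peptides <- function(proteins, params = digest_params()) {
  seqs <- as_sequence_vector(proteins)
  op <- vapply(seqs, function(s) {
    count_observable(tryptic_digest(s, params), params)
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(accession = names(seqs),
                 length = nchar(seqs),
                 op = op)
}

# normalize FASTA path / AAStringSet / named character to named character
as_sequence_vector <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    set <- Biostrings::readAAStringSet(proteins)
    seqs <- as.character(set)
    # FASTA headers may carry descriptions; accession = first token
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  if (methods::is(proteins, "AAStringSet")) {
    seqs <- as.character(proteins)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  if (is.character(proteins) && !is.null(names(proteins))) {
    return(proteins)
  }
  eq_abort("proteins must be a named character vector, AAStringSet, or FASTA path",
           "empaiq_invalid_input")
}
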