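# Readers/writers for the plain-text exchange formats. All tables are
# tab-separated with a header line; FASTA is 60-column wrapped.

# fail early with a clear message when a table lacks required columns
check_header <- function(path, required) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  missing <- setdiff(required, hdr)
  if (length(missing)) {
    eq_abort(sprintf("%s lacks required column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "empaiq_invalid_input")
  }
}

#' Read a spectral-count table
#'
#' @param path TSV with columns `accession`, `run_id`, `spectral_count`.
#' @return Tibble in long form.
#' @export
read_counts <- function(path) {
  check_header(path, c("accession", "run_id", "spectral_count"))
  readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    run_id = readr::col_character(),
    spectral_count = readr::col_integer()))
}

#' Read a run design table
#' @param path TSV with columns `run_id`, `strain`, `biomass`, `replicate`.
#' @return Tibble.
#' @export
read_design <- function(path) {
  check_header(path, c("run_id", "strain"))
  readr::read_tsv(path, col_types = readr::cols(
    run_id = readr::col_character(), strain = readr::col_character(),
    .default = readr::col_guess()))
}

#' Read a GO category map
#' @param path TSV with columns `accession`, `category`.
#' @return Tibble.
#' @export
read_go_map <- function(path) {
  check_header(path, c("accession", "category"))
  readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    category = readr::col_character()))
}

#' Read a Ct table
#' @param path TSV with columns `sample`, `gene`, `ct` (one row per
#'   replicate measurement).
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  check_header(path, c("sample", "gene", "ct"))
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), gene = readr::col_character(),
    ct = readr::col_double(), .default = readr::col_guess()))
}

#' Write a protein set as wrapped FASTA
#'
#' @param proteome Tibble with `accession`, `sequence` and optionally
#'   `description` (appended to the header after a space).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  headers <- proteome$accession
  if (!is.null(proteome$description)) {
    headers <- paste(headers, proteome$description)
  }
  set <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write all artifacts of a simulated study
#'
#' Emits the full input bundle for the pipeline: proteome FASTA, counts
#' TSV, design TSV, GO-map TSV, optional Ct TSV, and a JSON sidecar echoing
#' the simulation parameters and seed.
#'
#' @param proteome Tibble from [generate_proteome()].
#' @param sim `sc_simulation` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (echoed to `params.json`).
#' @param ct_table Optional tibble from [generate_ct_table()].
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(proteome, sim, dir, config = NULL,
                             ct_table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    go_map = file.path(dir, "go_map.tsv"),
    params = file.path(dir, "params.json")
  )
  write_proteome_fasta(proteome, paths$fasta)
  readr::write_tsv(sim$counts, paths$counts)
  readr::write_tsv(sim$design, paths$design)
  readr::write_tsv(proteome[, c("accession", "category")], paths$go_map)
  if (!is.null(ct_table)) {
    paths$ct <- file.path(dir, "ct.tsv")
    readr::write_tsv(ct_table[, c("sample", "gene", "ct")], paths$ct)
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paths$params, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(paths)
}
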