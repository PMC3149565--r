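#' Pipeline configuration
#'
#' Collects the file paths, digestion parameters, classification
#' thresholds, and histogram bin edges for one end-to-end run. All
#' under-specified analysis choices live here so that the echoed
#' configuration fully documents a run.
#'
#' @param fasta,counts,design,go_map Paths to the input files (FASTA,
#'   counts TSV, design TSV, GO-map TSV).
#' @param ct Optional path to a Ct TSV for the ddCt stage.
#' @param out_dir Output directory.
#' @param digest A [digest_params()] object.
#' @param reference_strain,test_strain Strain labels as used in the design
#'   table; ratios and calls are test vs reference.
#' @param alpha,up,down Classification thresholds (see
#'   [classify_protein()]); must satisfy `up > 1 > down > 0`.
#' @param pi_edges,mw_edges Histogram bin edges for the pI and Mw
#'   distributions (Mw in Da).
#' @param reference_gene,calibrator_sample ddCt settings (used only when
#'   `ct` is given).
#' @param sample_sd,var_equal,p_adjust Statistical switches, see
#'   [empai_summary()] and [call_table()].
#' @param seed Seed echoed into the run metadata (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, counts, design, go_map, ct = NULL,
                            out_dir = "empaiq_out",
                            digest = digest_params(),
                            reference_strain = "SP06081",
                            test_strain = "PR2",
                            alpha = 0.05, up = 1.5, down = 0.67,
                            pi_edges = seq(2, 14, by = 1),
                            mw_edges = seq(0, 200000, by = 10000),
                            reference_gene = "sigA",
                            calibrator_sample = "SP06081",
                            sample_sd = FALSE, var_equal = FALSE,
                            p_adjust = "none", seed = NA_integer_) {
  for (p in c(fasta, counts, design, go_map, ct)) {
    if (!file.exists(p)) {
      eq_abort(sprintf("input file does not exist: %s", p),
               "empaiq_invalid_config")
    }
  }
  if (!(up > 1 && down < 1 && down > 0 && alpha > 0 && alpha < 1)) {
    eq_abort("thresholds must satisfy up > 1 > down > 0 and 0 < alpha < 1",
             "empaiq_invalid_config")
  }
  structure(
    list(fasta = fasta, counts = counts, design = design, go_map = go_map,
         ct = ct, out_dir = out_dir, digest = digest,
         reference_strain = reference_strain, test_strain = test_strain,
         alpha = alpha, up = up, down = down,
         pi_edges = pi_edges, mw_edges = mw_edges,
         reference_gene = reference_gene,
         calibrator_sample = calibrator_sample,
         sample_sd = sample_sd, var_equal = var_equal,
         p_adjust = p_adjust, seed = seed),
    class = "pipeline_config"
  )
}

# md5 of the canonical JSON rendering of the config (identifies a run)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null", digits = NA, force = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full comparative analysis
#'
#' Executes every stage on the configured inputs: in silico digestion and
#' OP counting, per-strain emPAI quantification (MEP/MSD), shared/exclusive
#' set partition, interval differential calls with summary, functional
#' category profiles and between-strain fold changes, theoretical pI/Mw
#' histograms, and (when a Ct table is supplied) ddCt relative expression.
#' All result tables are written to `config$out_dir` as TSV plus two JSON
#' files (`summary.json`, `run_metadata.json` carrying the config echo,
#' its hash, and the seed). A failure in any stage removes the partial
#' outputs and re-raises the error tagged with the stage name.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with all in-memory results (`op_table`,
#'   `quant`, `partition`, `differential`, `profiles`, `fold_change`,
#'   `histograms`, `ddct`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    readr::write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "digestion"
    seqs <- as_sequence_vector(config$fasta)
    op_table <- observable_peptides(seqs, config$digest)
    emit(op_table, "op_table.tsv")

    stage <- "quantification"
    counts <- read_counts(config$counts)
    design <- read_design(config$design)
    quant <- quantify_strains(counts, design, op_table,
                              sample_sd = config$sample_sd)
    quant_ref <- quant[quant$strain == config$reference_strain, ]
    quant_test <- quant[quant$strain == config$test_strain, ]
    flat <- function(q) {
      q$run_values <- vapply(q$run_values, function(v) {
        paste(format(v, digits = 10, trim = TRUE, scientific = FALSE),
              collapse = ";")
      }, character(1))
      q
    }
    emit(flat(quant_ref), sprintf("quant_%s.tsv", config$reference_strain))
    emit(flat(quant_test), sprintf("quant_%s.tsv", config$test_strain))

    stage <- "partition"
    partition <- partition_sets(quant_ref$accession, quant_test$accession)
    emit(tibble::tibble(metric = names(partition$sizes),
                        value = as.integer(partition$sizes)),
         "partition_sizes.tsv")
    emit(tibble::tibble(accession = partition$exclusive_a),
         sprintf("exclusive_%s.tsv", config$reference_strain))
    emit(tibble::tibble(accession = partition$exclusive_b),
         sprintf("exclusive_%s.tsv", config$test_strain))

    stage <- "differential"
    diff <- call_table(quant_test, quant_ref, partition,
                       alpha = config$alpha, up = config$up,
                       down = config$down, var_equal = config$var_equal,
                       p_adjust = config$p_adjust)
    emit(diff$calls, "calls.tsv")
    summary_path <- file.path(out, "summary.json")
    jsonlite::write_json(diff$summary, summary_path, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, summary_path)

    stage <- "annotation"
    go_map <- read_go_map(config$go_map)
    prof_ref <- category_profile(quant_ref$accession, go_map)
    prof_test <- category_profile(quant_test$accession, go_map)
    profiles <- dplyr::bind_rows(
      dplyr::mutate(prof_ref, strain = config$reference_strain),
      dplyr::mutate(prof_test, strain = config$test_strain))
    emit(profiles, "category_profiles.tsv")
    fc <- category_fold_change(prof_test, prof_ref)
    emit(fc, "category_fold_change.tsv")

    stage <- "pi_mw"
    pis <- vapply(seqs, protein_pi, numeric(1), USE.NAMES = FALSE)
    mws <- vapply(seqs, protein_mw, numeric(1), USE.NAMES = FALSE)
    pi_hist <- distribution_bins(pis, config$pi_edges)
    mw_hist <- distribution_bins(mws, config$mw_edges)
    emit(pi_hist, "pi_histogram.tsv")
    emit(mw_hist, "mw_histogram.tsv")

    stage <- "ddct"
    dd <- NULL
    if (!is.null(config$ct)) {
      ct_table <- read_ct_table(config$ct)
      targets <- setdiff(unique(ct_table$gene), config$reference_gene)
      dd <- ddct_table(ct_table, targets, config$reference_gene,
                       config$calibrator_sample)
      emit(dd, "ddct.tsv")
    }

    stage <- "metadata"
    meta_path <- file.path(out, "run_metadata.json")
    jsonlite::write_json(
      list(config = unclass(config), config_md5 = config_hash(config),
           seed = config$seed,
           n_proteins = nrow(op_table),
           n_runs = nrow(design),
           package_version = as.character(utils::packageVersion("empaiq"))),
      meta_path, auto_unbox = TRUE, null = "null", digits = NA, force = TRUE)
    written <- c(written, meta_path)

    list(op_table = op_table, quant = quant, partition = partition,
         differential = diff,
         profiles = list(reference = prof_ref, test = prof_test),
         fold_change = fc,
         histograms = list(pi = pi_hist, mw = mw_hist),
         ddct = dd, files = written)
  }, error = function(e) {
    unlink(written)
    eq_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)),
             "empaiq_pipeline_error")
  })
  invisible(result)
}
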