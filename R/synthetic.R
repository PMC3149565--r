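#' Simulation configuration for a two-strain shotgun proteomics design
#'
#' Defines the study conditions the generator emulates: a reference strain
#' and a test strain, two biological biomasses each with three technical
#' LC-MS/MS replicates (six runs per strain), a proteome of a few hundred
#' proteins, planted multiplicative fold-change effects on designated
#' proteins, strain-exclusive proteins, and overdispersed spectral-count
#' noise. Defaults reproduce the published design: 288 proteins of which
#' 84 are exclusive to the reference strain and 64 to the test strain
#' (hence 140 shared), with 21 up- and 23 down-regulated plants.
#'
#' @param n_proteins Number of proteins in the database.
#' @param length_range Residue-count range (uniform draw); lower bound must
#'   be >= 30.
#' @param n_up,n_down Numbers of planted up-/down-regulated proteins (always
#'   drawn from the shared set).
#' @param effect_fold Multiplicative abundance ratio (test/reference) for
#'   planted proteins; must be > 0.
#' @param n_exclusive_a,n_exclusive_b Numbers of proteins exclusive to the
#'   reference (a) and test (b) strain.
#' @param base_abundance_range Range of expected spectral counts per run
#'   (log-uniform draw per protein) for a protein of reference size
#'   (`op_reference` observable peptides). A protein's actual expected
#'   count scales with its own observable-peptide count --- larger proteins
#'   yield more spectra, which is the size dependence emPAI normalizes
#'   away.
#' @param plant_abundance_range Like `base_abundance_range` but for the
#'   planted up-/down-regulated proteins: plants are placed in a
#'   moderately-abundant regime where the planted effect is measurable
#'   over six runs (the logic of a spike-in experiment).
#' @param plant_min_op Minimum observable-peptide count for a protein to
#'   carry a planted effect; a 5-fold depletion of a protein with only a
#'   handful of observable peptides falls below the per-run detection
#'   floor and no classifier could recover it.
#' @param op_reference Observable-peptide count of the "reference size"
#'   protein that `base_abundance_range` refers to.
#' @param dispersion Negative-binomial overdispersion `d` with
#'   `Var = mu + d * mu^2`; `d = 0` gives Poisson counts.
#' @param strains Character pair `c(reference, test)`.
#' @param n_biomass,n_tech Biological biomasses per strain and technical
#'   replicates per biomass (default 2 x 3 = 6 runs per strain).
#' @param exclusive_mode `"absent"` (default): exclusive proteins are
#'   structurally absent from the other strain (mean 0);
#'   `"dropout"`: present at a small fraction of their base abundance
#'   (`dropout_factor`), emulating sampling dropout instead of true absence.
#' @param dropout_factor Mean multiplier for `exclusive_mode = "dropout"`.
#' @param category_weights Optional weight vector over the 10 functional
#'   categories (defaults to uniform).
#' @param seed Integer RNG seed; every generator function derives its
#'   stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 288,
                       length_range = c(90, 900),
                       n_up = 21, n_down = 23,
                       effect_fold = 5,
                       n_exclusive_a = 84, n_exclusive_b = 64,
                       base_abundance_range = c(2, 15),
                       plant_abundance_range = c(10, 13),
                       plant_min_op = 50,
                       op_reference = 30,
                       dispersion = 0.05,
                       strains = c("SP06081", "PR2"),
                       n_biomass = 2, n_tech = 3,
                       exclusive_mode = c("absent", "dropout"),
                       dropout_factor = 0.02,
                       category_weights = NULL,
                       seed = 1) {
  exclusive_mode <- match.arg(exclusive_mode)
  bad <- function(field, why) {
    eq_abort(sprintf("invalid simulation config: %s %s", field, why),
             "empaiq_invalid_config")
  }
  if (n_proteins < 1 || n_proteins != floor(n_proteins)) {
    bad("n_proteins", "must be a positive integer")
  }
  if (length(length_range) != 2L || length_range[1] < 30 ||
      length_range[1] > length_range[2]) {
    bad("length_range", "must be c(lo, hi) with lo >= 30 residues")
  }
  if (n_up < 0 || n_down < 0) bad("n_up/n_down", "must be non-negative")
  if (effect_fold <= 0) bad("effect_fold", "must be > 0")
  if (n_exclusive_a < 0 || n_exclusive_b < 0) {
    bad("n_exclusive_a/n_exclusive_b", "must be non-negative")
  }
  if (n_up + n_down + n_exclusive_a + n_exclusive_b > n_proteins) {
    bad("n_up + n_down + n_exclusive_a + n_exclusive_b",
        "must not exceed n_proteins")
  }
  if (length(base_abundance_range) != 2L || base_abundance_range[1] <= 0 ||
      base_abundance_range[1] > base_abundance_range[2]) {
    bad("base_abundance_range", "must be c(lo, hi) with lo > 0")
  }
  if (length(plant_abundance_range) != 2L ||
      plant_abundance_range[1] <= 0 ||
      plant_abundance_range[1] > plant_abundance_range[2]) {
    bad("plant_abundance_range", "must be c(lo, hi) with lo > 0")
  }
  if (plant_min_op < 1) bad("plant_min_op", "must be >= 1")
  if (op_reference < 1) bad("op_reference", "must be >= 1")
  if (dispersion < 0) bad("dispersion", "must be >= 0")
  if (length(strains) != 2L || anyDuplicated(strains)) {
    bad("strains", "must be two distinct strain names")
  }
  if (!is.null(category_weights) &&
      (length(category_weights) != 10L || any(category_weights < 0) ||
       sum(category_weights) <= 0)) {
    bad("category_weights", "must be 10 non-negative weights")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         effect_fold = effect_fold,
         n_exclusive_a = as.integer(n_exclusive_a),
         n_exclusive_b = as.integer(n_exclusive_b),
         base_abundance_range = as.numeric(base_abundance_range),
         plant_abundance_range = as.numeric(plant_abundance_range),
         plant_min_op = as.integer(plant_min_op),
         op_reference = as.integer(op_reference),
         dispersion = dispersion,
         strains = as.character(strains),
         n_biomass = as.integer(n_biomass), n_tech = as.integer(n_tech),
         exclusive_mode = exclusive_mode,
         dropout_factor = dropout_factor,
         category_weights = category_weights,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# residue sampling weights: uniform background with K/R enriched so that
# average tryptic fragments fall inside the default scan window and every
# protein has at least one observable peptide
residue_weights <- function() {
  w <- stats::setNames(rep(1, 20), AA_ALPHABET)
  w[c("K", "R")] <- 1.6
  w / sum(w)
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` i.i.d.-residue sequences (uniform background with
#' mildly enriched K/R content) and rejects the rare sequence with no
#' observable tryptic peptide under the default 600-3500 Da window, so
#' emPAI is defined for every protein. Each protein is assigned one of the
#' 10 functional categories (uniformly, or per `category_weights`).
#'
#' @param config A [sim_config()] object.
#' @return Tibble `accession`, `description`, `sequence`, `length`,
#'   `category`, `op` (observable peptides under the default window).
#' @export
generate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  w <- residue_weights()
  params <- digest_params()
  cats <- functional_categories()
  cw <- config$category_weights
  if (is.null(cw)) cw <- rep(1, length(cats))
  withr::with_seed(config$seed, {
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   config$n_proteins, replace = TRUE)
    seqs <- character(config$n_proteins)
    ops <- integer(config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      repeat {
        s <- paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = w),
                   collapse = "")
        min_kr <- max(1L, lens[i] %/% 40L)
        kr <- sum(strsplit(s, "")[[1]] %in% c("K", "R"))
        if (kr < min_kr) next
        op <- count_observable(tryptic_digest(s, params), params)
        if (op >= 1L) {
          seqs[i] <- s
          ops[i] <- op
          break
        }
      }
    }
    category <- sample(cats, config$n_proteins, replace = TRUE, prob = cw)
  })
  accession <- sprintf("SYN%04d", seq_len(config$n_proteins))
  tibble::tibble(
    accession = accession,
    description = sprintf("synthetic protein %d, %s", seq_along(accession),
                          category),
    sequence = seqs,
    length = nchar(seqs),
    category = category,
    op = ops
  )
}

# deterministic role assignment: planted effects go to proteins with
# op >= plant_min_op (where a 5-fold change is observable over six runs);
# exclusives are drawn from the remaining proteins
assign_roles <- function(config, op) {
  n_plant <- config$n_up + config$n_down
  n_excl <- config$n_exclusive_a + config$n_exclusive_b
  eligible <- which(op >= config$plant_min_op)
  if (length(eligible) < n_plant) {
    eq_abort(sprintf(
      paste0("only %d proteins have op >= plant_min_op (%d) but %d planted ",
             "effects requested; enlarge the proteome or lower plant_min_op"),
      length(eligible), config$plant_min_op, n_plant),
      "empaiq_invalid_config")
  }
  role <- rep("constant", config$n_proteins)
  withr::with_seed(config$seed + 1L, {
    plant <- eligible[sample.int(length(eligible), n_plant)]
    rest <- setdiff(seq_len(config$n_proteins), plant)
    excl <- rest[sample.int(length(rest), n_excl)]
  })
  role[plant[seq_len(config$n_up)]] <- "up"
  role[plant[config$n_up + seq_len(config$n_down)]] <- "down"
  role[excl[seq_len(config$n_exclusive_a)]] <- "exclusive_a"
  role[excl[config$n_exclusive_a + seq_len(config$n_exclusive_b)]] <-
    "exclusive_b"
  role
}

#' Simulate a spectral-count matrix
#'
#' Draws spectral counts for every (protein, run) pair from a negative
#' binomial (Poisson when `dispersion = 0`). The expected count is
#' `base x op / op_reference x strain effect`: `base` is the protein's
#' abundance draw (expected spectral counts per run at reference size) and
#' the `op / op_reference` factor makes larger proteins yield
#' proportionally more spectra, the size dependence that dividing SC by OP
#' in emPAI corrects. Planted up-proteins have their mean multiplied by
#' `effect_fold` in the test strain, down-proteins divided; exclusive
#' proteins have mean 0 (or `dropout_factor` x base, in dropout mode) in
#' all runs of the other strain.
#'
#' @param proteome Tibble from [generate_proteome()].
#' @param config A [sim_config()] object.
#' @return List of class `sc_simulation` with `counts` (long tibble
#'   `accession`, `run_id`, `spectral_count`), `design` (tibble `run_id`,
#'   `strain`, `biomass`, `replicate`), and `truth` (tibble `accession`,
#'   `role`, `base_abundance`).
#' @export
simulate_counts <- function(proteome, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(proteome)) {
    eq_abort("proteome must be nonempty", "empaiq_invalid_input")
  }
  if (nrow(proteome) != config$n_proteins) {
    eq_abort("proteome size does not match config$n_proteins",
             "empaiq_invalid_config")
  }
  ref <- config$strains[1]; test <- config$strains[2]
  design <- expand.grid(replicate = seq_len(config$n_tech),
                        biomass = seq_len(config$n_biomass),
                        strain = config$strains,
                        stringsAsFactors = FALSE)
  design <- tibble::tibble(
    run_id = sprintf("%s_b%d_t%d", design$strain, design$biomass,
                     design$replicate),
    strain = design$strain, biomass = design$biomass,
    replicate = design$replicate
  )
  op <- proteome$op
  if (is.null(op)) {
    op <- observable_peptides(
      stats::setNames(proteome$sequence, proteome$accession))$op
  }
  role <- assign_roles(config, op)
  other_factor <- if (config$exclusive_mode == "absent") 0 else
    config$dropout_factor

  withr::with_seed(config$seed + 2L, {
    lo <- log(config$base_abundance_range[1])
    hi <- log(config$base_abundance_range[2])
    base <- exp(stats::runif(config$n_proteins, lo, hi))
    plo <- log(config$plant_abundance_range[1])
    phi <- log(config$plant_abundance_range[2])
    planted <- role %in% c("up", "down")
    base[planted] <- exp(stats::runif(sum(planted), plo, phi))
    n_runs <- nrow(design)
    # per-protein mean per run, scaled by protein size (observable peptides)
    size_factor <- op / config$op_reference
    mean_ref <- base * size_factor *
      ifelse(role == "exclusive_b", other_factor, 1)
    mean_test <- base * size_factor *
      ifelse(role == "up", config$effect_fold,
      ifelse(role == "down", 1 / config$effect_fold,
      ifelse(role == "exclusive_a", other_factor, 1)))
    mu <- outer(seq_len(config$n_proteins), seq_len(n_runs),
                function(i, j) {
                  ifelse(design$strain[j] == ref, mean_ref[i], mean_test[i])
                })
    counts <- if (config$dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    counts[mu == 0] <- 0L   # rnbinom(mu = 0) is 0, but keep it explicit
    dim(counts) <- dim(mu)
  })

  long <- tibble::tibble(
    accession = rep(proteome$accession, times = nrow(design)),
    run_id = rep(design$run_id, each = nrow(proteome)),
    spectral_count = as.integer(counts)
  )
  structure(
    list(counts = long, design = design,
         truth = tibble::tibble(accession = proteome$accession,
                                role = role, base_abundance = base,
                                op = op,
                                mean_sc_ref = mean_ref,
                                mean_sc_test = mean_test)),
    class = "sc_simulation"
  )
}

#' Generate a synthetic Ct table for ddCt confirmation
#'
#' Builds threshold-cycle values for target genes and a reference gene in a
#' calibrator and a test sample such that delta-delta-Ct back-calculation
#' recovers the requested fold changes exactly at zero noise:
#' the test-sample target Ct is lowered by `log2(fold)` cycles relative to
#' the calibrator (reference-gene-adjusted).
#'
#' @param genes Character vector of target gene names.
#' @param fold_changes Positive fold changes (test/calibrator), recycled to
#'   `length(genes)`.
#' @param seed RNG seed for the Gaussian Ct noise.
#' @param noise_sd Standard deviation of Ct noise in cycles (default 0).
#' @param n_replicates Replicate measurements per (sample, gene).
#' @param reference_gene,calibrator_sample,test_sample Labels used in the
#'   table.
#' @return Tibble `sample`, `gene`, `replicate`, `ct`.
#' @export
generate_ct_table <- function(genes, fold_changes, seed = 1, noise_sd = 0,
                              n_replicates = 6, reference_gene = "sigA",
                              calibrator_sample = "SP06081",
                              test_sample = "PR2") {
  if (any(fold_changes <= 0)) {
    eq_abort("fold_changes must be positive", "empaiq_invalid_config")
  }
  fold_changes <- rep_len(fold_changes, length(genes))
  ref_ct <- 18
  base_ct <- 22 + (seq_along(genes) - 1) %% 5   # spread target baselines
  rows <- list()
  add <- function(smp, gene, ct0) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      sample = smp, gene = gene, replicate = seq_len(n_replicates),
      ct = ct0 + if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd)
           else rep(0, n_replicates))
  }
  withr::with_seed(seed, {
    add(calibrator_sample, reference_gene, ref_ct)
    add(test_sample, reference_gene, ref_ct)
    for (g in seq_along(genes)) {
      add(calibrator_sample, genes[g], base_ct[g])
      add(test_sample, genes[g], base_ct[g] - log2(fold_changes[g]))
    }
  })
  dplyr::bind_rows(rows)
}
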