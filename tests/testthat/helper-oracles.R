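# Independent brute-force oracles used across the suite. These deliberately
# take a different computational route than the package internals.

# enumerate tryptic products by checking every substring against the
# cleavage-boundary definition (quadratic, for small proteins only)
brute_digest <- function(sequence, missed = 0, proline_rule = TRUE) {
  n <- nchar(sequence)
  pat <- if (proline_rule) "[KR](?!P)" else "[KR]"
  hits <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  sites <- if (hits[1] == -1) integer(0) else as.integer(hits)
  sites <- sites[sites < n]                  # no cleavage after last residue
  boundaries <- c(0L, sites, n)
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!((i - 1L) %in% boundaries) || !(j %in% boundaries)) next
      internal <- sum(sites > (i - 1L) & sites < j)
      if (internal <= missed) out <- c(out, substr(sequence, i, j))
    }
  }
  out
}

# isoelectric point via uniroot on the Henderson-Hasselbalch net charge,
# written independently of the package's counting/bisection code
oracle_pi <- function(sequence, tol = 1e-7) {
  pk_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pk_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  res <- strsplit(sequence, "")[[1]]
  charge <- function(ph) {
    q <- 1 / (1 + 10^(ph - pk_pos["Nterm"])) -
      1 / (1 + 10^(pk_neg["Cterm"] - ph))
    for (a in c("K", "R", "H")) {
      q <- q + sum(res == a) / (1 + 10^(ph - pk_pos[a]))
    }
    for (a in c("D", "E", "C", "Y")) {
      q <- q - sum(res == a) / (1 + 10^(pk_neg[a] - ph))
    }
    q
  }
  stats::uniroot(charge, c(0, 14), tol = tol)$root
}

# closed-form delta-delta-Ct: fold = 2^-((Ct_t,test - Ct_r,test) -
# (Ct_t,cal - Ct_r,cal))
oracle_ddct <- function(ct_t_test, ct_r_test, ct_t_cal, ct_r_cal) {
  2^(-((ct_t_test - ct_r_test) - (ct_t_cal - ct_r_cal)))
}

# random canonical protein sequence
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# construct counts/design/op tables for a two-strain toy study from a
# matrix of per-run spectral counts (rows = proteins, 6 ref + 6 test runs)
toy_study <- function(sc_matrix, op, ref = "SP06081", test = "PR2") {
  n_runs <- ncol(sc_matrix)
  stopifnot(n_runs %% 2 == 0)
  half <- n_runs / 2
  design <- tibble::tibble(
    run_id = sprintf("r%02d", seq_len(n_runs)),
    strain = rep(c(ref, test), each = half),
    biomass = rep(rep(1:2, each = ceiling(half / 2), length.out = half), 2),
    replicate = rep(seq_len(half), 2)
  )
  acc <- sprintf("P%03d", seq_len(nrow(sc_matrix)))
  counts <- tibble::tibble(
    accession = rep(acc, times = n_runs),
    run_id = rep(design$run_id, each = nrow(sc_matrix)),
    spectral_count = as.integer(sc_matrix)
  )
  list(counts = counts, design = design,
       op_table = tibble::tibble(accession = acc, op = op),
       accessions = acc)
}
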