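test_that("category assignment falls back to 'no description'", {
  go_map <- tibble::tibble(accession = c("a", "b"),
                           category = c("glycolysis", "translation"))
  expect_identical(assign_category(c("a", "b", "zz"), go_map),
                   c("glycolysis", "translation", "no description"))
})

test_that("category profile counts match construction and normalize", {
  set.seed(71)
  cats <- functional_categories()
  acc <- sprintf("p%03d", 1:224)
  # plant exactly 34 biosynthetic-process proteins among 224
  assigned <- c(rep("biosynthetic process", 34),
                sample(setdiff(cats, "biosynthetic process"), 190,
                       replace = TRUE))
  go_map <- tibble::tibble(accession = acc, category = assigned)
  prof <- category_profile(acc, go_map)
  expect_identical(prof$count[prof$category == "biosynthetic process"], 34L)
  expect_identical(round(
    prof$percentage[prof$category == "biosynthetic process"]), 15)
  expect_equal(sum(prof$percentage), 100, tolerance = 0.1)
  expect_identical(sum(prof$count), 224L)
  # single-category set
  one <- category_profile(c("a", "b"),
                          tibble::tibble(accession = c("a", "b"),
                                         category = "transport"))
  expect_identical(one$percentage[one$category == "transport"], 100)
  expect_error(category_profile(character(0), go_map),
               class = "empaiq_invalid_input")
})

test_that("category fold changes: identity, ratio, reciprocity, zeros", {
  cats <- functional_categories()
  map1 <- tibble::tibble(accession = sprintf("x%02d", 1:20),
                         category = rep(cats, 2))
  p1 <- category_profile(map1$accession, map1)
  self <- category_fold_change(p1, p1)
  expect_true(all(self$fold_change[self$pct_ref > 0] == 1))
  # 20% vs 10% translation
  mapA <- tibble::tibble(accession = sprintf("a%02d", 1:10),
                         category = c(rep("translation", 1),
                                      rep("transport", 9)))
  mapB <- tibble::tibble(accession = sprintf("b%02d", 1:10),
                         category = c(rep("translation", 2),
                                      rep("transport", 8)))
  pa <- category_profile(mapA$accession, mapA)
  pb <- category_profile(mapB$accession, mapB)
  fc <- category_fold_change(pb, pa)
  expect_equal(fc$fold_change[fc$category == "translation"], 2)
  # reciprocity where both sides are positive
  rev <- category_fold_change(pa, pb)
  both <- !is.na(fc$fold_change) & !is.na(rev$fold_change) &
    fc$fold_change > 0
  expect_equal(rev$fold_change[both], 1 / fc$fold_change[both])
  # zero reference percentage -> NA, not Inf
  expect_true(all(is.na(fc$fold_change[fc$pct_ref == 0 & fc$pct_test > 0])))
})

test_that("pI ordering, root condition, and oracle agreement", {
  expect_gt(protein_pi("KKKKKKKK"), protein_pi("DDDDDDDD"))
  probe <- "ACDEFGHIKLMNPQRSTVWY"
  expect_lt(abs(protein_pi(probe) - oracle_pi(probe)), 0.02)
  set.seed(72)
  for (i in 1:100) {
    s <- random_protein(sample(20:200, 1))
    pi_hat <- protein_pi(s)
    expect_lt(abs(pi_hat - oracle_pi(s)), 0.02)
  }
  # net charge at the returned pI is numerically zero
  chars <- strsplit(probe, "")[[1]]
  counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                   function(a) sum(chars == a), numeric(1))
  expect_lt(abs(empaiq:::protein_charge(counts, protein_pi(probe))), 1e-3)
})

test_that("distribution bins tally like a brute-force loop", {
  set.seed(73)
  edges <- c(0, 2, 4, 6, 10)
  vals <- runif(200, 0, 10)
  got <- distribution_bins(vals, edges)
  brute <- vapply(seq_len(length(edges) - 1), function(i) {
    if (i < length(edges) - 1) {
      sum(vals >= edges[i] & vals < edges[i + 1])
    } else {
      sum(vals >= edges[i] & vals <= edges[i + 1])
    }
  }, numeric(1))
  expect_identical(as.numeric(got$count), brute)
  expect_identical(sum(got$count), 200L)
  expect_equal(sum(got$percentage), 100)
  # final edge is included, first bin is right-open
  at_edges <- distribution_bins(c(0, 2, 10), edges)
  expect_identical(as.integer(at_edges$count), c(1L, 1L, 0L, 1L))
  # single bin takes everything
  expect_identical(distribution_bins(c(1, 2, 3), c(0, 5))$percentage, 100)
  expect_error(distribution_bins(1:3, c(5, 1)),
               class = "empaiq_invalid_input")
})
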