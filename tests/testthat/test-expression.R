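test_that("stage means average the named columns over all genes", {
  m <- matrix(c(10, 0, 30, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("sA", "sB")))
  expect_equal(stage_mean(m, "sA"), c(g1 = 10, g2 = 0))
  expect_equal(stage_mean(m, c("sA", "sB")), c(g1 = 20, g2 = 2))
  # idempotence over identical columns
  m2 <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(m2) <- c("x", "y", "z")
  expect_equal(stage_mean(m2, c("x", "y", "z")), c(g1 = 10, g2 = 0))
  expect_error(stage_mean(m, "nope"), "unknown stage.*sA")
})

test_that("percentile threshold uses linear interpolation over all genes", {
  expect_equal(percentile_threshold(0:99, 25), 24.75)
  expect_equal(percentile_threshold(c(5, 5, 5, 5), 25), 5)
  expect_error(percentile_threshold(numeric(0), 25), "empty")
  # order invariance and scale equivariance
  set.seed(1)
  v <- rexp(200) * 10
  expect_equal(percentile_threshold(sample(v), 25),
               percentile_threshold(v, 25))
  expect_equal(percentile_threshold(3 * v, 25),
               3 * percentile_threshold(v, 25))
})

test_that("verdicts apply a strict comparison at the threshold", {
  means <- c(below = 10, at = 24.75, above = 25, top = 99)
  v <- expression_verdicts(c(means, setNames(0:95, paste0("f", 0:95))),
                           percentile = 25)
  # threshold from the combined vector; boundary gene excluded by '>'
  expect_false(v$pass[v$gene_id == "at"] &&
                 v$mean[v$gene_id == "at"] == v$threshold[1])
  vo <- expression_verdicts(means, threshold = 24.75)
  expect_equal(vo$pass, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("pseudobulk sums per cluster then averages across clusters", {
  sc <- matrix(1:12, 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  labels <- setNames(c("k1", "k1", "k2", "k2"), paste0("c", 1:4))
  got <- pseudobulk_mean(sc, labels, c("k1", "k2"))
  # oracle: explicit double loop
  want <- sapply(paste0("g", 1:3), function(g) {
    sums <- sapply(c("k1", "k2"), function(k) {
      cells <- names(labels)[labels == k]
      tot <- 0
      for (cell in cells) tot <- tot + sc[g, cell]
      tot
    })
    mean(sums)
  })
  expect_equal(got, want)
  expect_equal(pseudobulk_mean(sc, labels, "k1"),
               rowSums(sc[, 1:2]))
  expect_error(pseudobulk_mean(sc, labels, "k9"), "k9")
})

test_that("random pseudobulk agrees with a naive double-loop oracle", {
  set.seed(77)
  sc <- matrix(rpois(25 * 30, 4), 25, 30,
               dimnames = list(paste0("g", 1:25), paste0("c", 1:30)))
  labels <- setNames(sample(c("a", "b", "d"), 30, replace = TRUE),
                     colnames(sc))
  got <- pseudobulk_mean(sc, labels, c("a", "d"))
  want <- numeric(25)
  for (gi in 1:25) {
    sums <- c(0, 0)
    for (ci in 1:30) {
      if (labels[ci] == "a") sums[1] <- sums[1] + sc[gi, ci]
      if (labels[ci] == "d") sums[2] <- sums[2] + sc[gi, ci]
    }
    want[gi] <- mean(sums)
  }
  expect_equal(unname(got), want)
})

test_that("TFBS gating retains sites with expressed TFs and audits the rest", {
  conserved <- data.frame(motif_id = c("M1", "M2", "M3", "M4"),
                          cncs_id = "C1", ref_start = 1:4,
                          ref_strand = "+", ref_score = 0.9,
                          ref_norm_pos = 0.5, mean_norm_pos = 0.5,
                          max_deviation = 0.01, n_species = 5)
  tf_map <- list(M1 = "tfA", M2 = "tfB", M3 = c("tfC", "tfD"))
  bulk <- data.frame(gene_id = c("tfA", "tfB", "tfC", "tfD"),
                     mean = c(100, 100, 1, 100), threshold = 17,
                     pass = c(TRUE, TRUE, FALSE, TRUE))
  sc <- data.frame(gene_id = c("tfA", "tfB", "tfC", "tfD"),
                   mean = c(900, 10, 900, 900), threshold = 250,
                   pass = c(TRUE, FALSE, TRUE, TRUE))
  both <- gate_tfbs(conserved, tf_map, bulk, sc, mode = "bulk_and_sc")
  # M1 passes both; M2 fails sc; M3 passes via tfD; M4 unmapped
  expect_setequal(both$retained$motif_id, c("M1", "M3"))
  expect_equal(both$audit$reason[both$audit$motif_id == "M2"], "expression")
  expect_equal(both$audit$reason[both$audit$motif_id == "M4"], "unmapped")

  bulk_only <- gate_tfbs(conserved, tf_map, bulk, mode = "bulk_only")
  expect_setequal(bulk_only$retained$motif_id, c("M1", "M2", "M3"))
  # sequential refinement: bulk_and_sc output is a subset of bulk_only
  expect_true(all(both$retained$motif_id %in% bulk_only$retained$motif_id))
  expect_error(gate_tfbs(conserved, tf_map, bulk, mode = "bulk_and_sc"),
               "requires")
})

test_that("percentile path equals fixed-threshold path on calibrated data", {
  # transcriptome constructed so the 25th percentile is exactly 17 and the
  # 50th exactly 250: thresholds then reduce to plain comparisons
  bulk_v <- c(seq(0, 17, length.out = 76), seq(17.5, 1000, length.out = 225))
  names(bulk_v) <- paste0("g", seq_along(bulk_v))
  expect_equal(percentile_threshold(bulk_v, 25), 17)
  sc_v <- c(seq(0, 250, length.out = 151), seq(251, 5000, length.out = 150))
  names(sc_v) <- paste0("h", seq_along(sc_v))
  expect_equal(percentile_threshold(sc_v, 50), 250)
  via_pct <- expression_verdicts(bulk_v, percentile = 25)
  via_abs <- expression_verdicts(bulk_v, threshold = 17)
  expect_equal(via_pct$pass, via_abs$pass)
})
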