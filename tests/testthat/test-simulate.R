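test_that("promoter simulation is deterministic and respects zero rates", {
  cfg <- promoter_sim_config(n_species = 3, promoter_length = 1200,
                             blocks = data.frame(start = 200, length = 300,
                                                 rate = 0),
                             background_rate = 0, indel_rate = 0,
                             motifs = list(list(consensus = "TTGACCTGAGTC",
                                                block = 1, rel_pos = 0.5,
                                                species = NULL)),
                             seed = 4)
  a <- simulate_promoters(cfg)
  b <- simulate_promoters(cfg)
  expect_identical(a$sequences, b$sequences)
  # zero rates: all species identical, consensus present verbatim
  expect_equal(length(unique(a$sequences)), 1L)
  expect_true(all(grepl("TTGACCTGAGTC", a$sequences, fixed = TRUE)))
  # truth records the planted instance in every species
  expect_equal(nrow(a$truth$motifs), 3L)
  for (i in seq_len(3)) {
    m <- a$truth$motifs[i, ]
    expect_equal(unname(substr(a$sequences[m$species], m$start + 1, m$start + 12)),
                 "TTGACCTGAGTC")
  }
})

test_that("realized block divergence matches the binomial expectation", {
  rates <- numeric(20)
  for (seed in 1:20) {
    cfg <- promoter_sim_config(n_species = 2, promoter_length = 1000,
                               blocks = data.frame(start = 300, length = 300,
                                                   rate = 0.02),
                               background_rate = 0.4, indel_rate = 0,
                               seed = seed)
    sim <- simulate_promoters(cfg)
    ref <- strsplit(sim$sequences[1], "")[[1]][301:600]
    oth <- strsplit(sim$sequences[2], "")[[1]][301:600]
    rates[seed] <- mean(ref == oth)
  }
  # substitutions hit a site w.p. 0.02 and always change the base
  expected <- 1 - 0.02
  se <- sqrt(0.02 * 0.98 / 300) # per-replicate sd of realized identity
  expect_lt(abs(mean(rates) - expected), 3 * se / sqrt(20))
})

test_that("motifs planted in a species subset are absent elsewhere", {
  cons <- "GGATTACCGTAA"
  cfg <- promoter_sim_config(n_species = 4, promoter_length = 2000,
                             blocks = data.frame(start = 500, length = 300,
                                                 rate = 0),
                             background_rate = 0.1, indel_rate = 0,
                             motifs = list(list(consensus = cons, block = 1,
                                                rel_pos = 0.4,
                                                species = paste0("species_",
                                                                 1:3))),
                             seed = 8)
  sim <- simulate_promoters(cfg)
  expect_true(all(grepl(cons, sim$sequences[1:3], fixed = TRUE)))
  expect_false(grepl(cons, sim$sequences[4], fixed = TRUE))
  expect_setequal(unique(sim$truth$motifs$species), paste0("species_", 1:3))
})

test_that("colliding planted motifs are rejected at config time", {
  expect_error(promoter_sim_config(
    motifs = list(list(consensus = "AAAAAAAAAA", block = 1, rel_pos = 0.50),
                  list(consensus = "CCCCCCCCCC", block = 1, rel_pos = 0.51))),
    "collide")
  expect_error(promoter_sim_config(
    blocks = data.frame(start = c(0, 100), length = c(200, 100),
                        rate = 0.02)), "overlap")
})

test_that("simulated sequences survive a FASTA round trip", {
  sim <- simulate_promoters(promoter_sim_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$sequences, f)
  expect_equal(read_fasta(f), sim$sequences)
})

test_that("expression simulation honors the expressed sets by construction", {
  tfs <- paste0("tf", 1:6)
  sim <- simulate_expression(tfs, expressed_set = tfs[1:3],
                             sc_expressed_set = tfs[c(1, 2)],
                             n_filler = 400, seed = 5)
  bulk_v <- expression_verdicts(stage_mean(sim$bulk, colnames(sim$bulk)),
                                percentile = 25)
  sc_v <- expression_verdicts(
    pseudobulk_mean(sim$sc, sim$cluster_labels,
                    unique(sim$cluster_labels)), percentile = 50)
  got_bulk <- bulk_v$gene_id[bulk_v$pass & bulk_v$gene_id %in% tfs]
  expect_setequal(got_bulk, tfs[1:3])
  got_sc <- sc_v$gene_id[sc_v$pass & sc_v$gene_id %in% tfs]
  expect_setequal(got_sc, tfs[c(1, 2)])
  # tf3 is bulk-expressed but silent in the clusters: dropped in bulk_and_sc
  conserved <- data.frame(motif_id = paste0("M", 1:6), cncs_id = "C1",
                          ref_start = 1:6, ref_strand = "+",
                          ref_score = 0.9, ref_norm_pos = 0.5,
                          mean_norm_pos = 0.5, max_deviation = 0.01,
                          n_species = 5)
  tf_map <- setNames(as.list(tfs), paste0("M", 1:6))
  gated <- gate_tfbs(conserved, tf_map, bulk_v, sc_v, mode = "bulk_and_sc")
  expect_setequal(gated$retained$motif_id, c("M1", "M2"))
  expect_warning(simulate_expression("tf1", n_filler = 50, seed = 1),
                 "filler")
})

test_that("ortholog simulation is deterministic with mutual-best scores", {
  a <- simulate_orthologs(seed = 6)
  b <- simulate_orthologs(seed = 6)
  expect_identical(a, b)
  cs <- compute_c_scores(a$hits)
  expect_true(all(cs$c_score == 1))
  # noise 1: chromosomes uniform, truth map ignored
  n <- simulate_orthologs(n_chrom_A = 3, n_chrom_B = 3, n_pairs = 3000,
                          noise_fraction = 1, seed = 7)
  tab <- table(n$chromA)
  expect_true(all(abs(tab / 3000 - 1 / 3) < 0.05))
})
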