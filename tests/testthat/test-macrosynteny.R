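test_that("C-scores divide by the larger of the two genes' best scores", {
  hits <- data.frame(geneA = c("a1", "a1", "a2"),
                     geneB = c("b1", "b2", "b1"),
                     score = c(100, 80, 90))
  cs <- compute_c_scores(hits)
  expect_equal(cs$c_score[1], 1.0)          # mutual best
  expect_equal(cs$c_score[2], 80 / 100)     # a1's best is 100
  expect_equal(cs$c_score[3], 90 / 100)     # b1's best is 100
  expect_error(compute_c_scores(hits[0, ]), "empty")
})

test_that("random hit tables match a naive per-gene max oracle", {
  set.seed(91)
  for (rep in 1:10) {
    hits <- data.frame(
      geneA = sample(paste0("a", 1:8), 30, replace = TRUE),
      geneB = sample(paste0("b", 1:8), 30, replace = TRUE),
      score = round(runif(30, 10, 100), 2))
    hits <- hits[!duplicated(hits[, 1:2]), ]
    cs <- compute_c_scores(hits)
    for (i in seq_len(nrow(hits))) {
      bestA <- max(hits$score[hits$geneA == hits$geneA[i]])
      bestB <- max(hits$score[hits$geneB == hits$geneB[i]])
      expect_equal(cs$c_score[i], hits$score[i] / max(bestA, bestB))
    }
  }
})

test_that("C-score filtering is inclusive at the threshold and monotone", {
  hits <- data.frame(geneA = c("a1", "a1"), geneB = c("b1", "b2"),
                     score = c(100, 99))
  chromA <- c(a1 = "A1")
  chromB <- c(b1 = "B1", b2 = "B2")
  kept99 <- filter_pairs(compute_c_scores(hits), chromA, chromB, 0.99)
  expect_equal(nrow(kept99$pairs), 2L)  # 0.99 kept inclusively
  kept999 <- filter_pairs(compute_c_scores(hits), chromA, chromB, 0.995)
  expect_equal(nrow(kept999$pairs), 1L)
  kept7 <- filter_pairs(compute_c_scores(hits), chromA, chromB, 0.7)
  expect_gte(nrow(kept7$pairs), nrow(kept99$pairs))
  # unassigned genes are audited out
  audited <- filter_pairs(compute_c_scores(hits), chromA,
                          c(b1 = "B1"), 0.7)
  expect_equal(nrow(audited$audit), 1L)
  expect_equal(audited$audit$geneB, "b2")
})

test_that("two-chromosome split gives the closed-form hypergeometric p", {
  # 100 pairs, 50 on (A1,B1) and 50 on (A2,B2): for (A1,B1) the one-sided
  # p is P(X >= 50) with X ~ Hypergeom(m=50, n=50, k=50) = 1/C(100,50)
  sim <- data.frame(chromA = rep(c("A1", "A2"), each = 50),
                    chromB = rep(c("B1", "B2"), each = 50))
  res <- correspondence_test(sim, alpha = 0.05)
  t11 <- res$tests[res$tests$chromA == "A1" & res$tests$chromB == "B1", ]
  expect_equal(t11$p_raw, 1 / choose(100, 50), tolerance = 1e-10)
  expect_equal(t11$p_adjusted, t11$p_raw * res$bonferroni_factor)
  expect_true(t11$significant)
  expect_true(all(res$tests$n11 + res$tests$n12 + res$tests$n21 +
                    res$tests$n22 == 100))
})

test_that("raw p-values equal brute-force hypergeometric tail sums", {
  set.seed(92)
  for (rep in 1:5) {
    pairs <- data.frame(
      chromA = sample(paste0("A", 1:4), 120, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)),
      chromB = sample(paste0("B", 1:4), 120, replace = TRUE))
    res <- correspondence_test(pairs, alpha = 0.05)
    for (i in seq_len(nrow(res$tests))) {
      t <- res$tests[i, ]
      expect_equal(t$p_raw,
                   oracle_fisher_greater(t$n11, t$n12, t$n21, t$n22),
                   tolerance = 1e-9)
    }
  }
})

test_that("margins reconstruct and species swap transposes the result", {
  set.seed(93)
  pairs <- data.frame(chromA = sample(paste0("A", 1:3), 60, replace = TRUE),
                      chromB = sample(paste0("B", 1:3), 60, replace = TRUE))
  res <- correspondence_test(pairs, alpha = 0.05)
  tab <- table(pairs$chromA, pairs$chromB)
  for (i in seq_len(nrow(res$tests))) {
    t <- res$tests[i, ]
    expect_equal(t$n11 + t$n12, sum(tab[t$chromA, ]))
    expect_equal(t$n11 + t$n21, sum(tab[, t$chromB]))
  }
  swapped <- correspondence_test(
    data.frame(chromA = pairs$chromB, chromB = pairs$chromA), alpha = 0.05)
  key <- function(r, rev = FALSE) {
    a <- if (rev) r$chromB else r$chromA
    b <- if (rev) r$chromA else r$chromB
    o <- order(a, b)
    list(paste(a, b)[o], r$p_raw[o])
  }
  expect_equal(key(res$tests), key(swapped$tests, rev = TRUE))
})

test_that("a single chromosome per species is degenerate and non-significant", {
  pairs <- data.frame(chromA = rep("A1", 40),
                      chromB = sample(paste0("B", 1:4), 40, replace = TRUE))
  res <- correspondence_test(pairs, alpha = 0.05)
  expect_true(all(res$tests$p_raw == 1))
  expect_false(any(res$tests$significant))
})

test_that("noise-free simulated orthologs recover the true map end-to-end", {
  sim <- simulate_orthologs(n_chrom_A = 6, n_chrom_B = 6, n_pairs = 300,
                            noise_fraction = 0, seed = 17)
  res <- run_synteny(sim$hits, sim$chromA, sim$chromB, c_threshold = 0.99,
                     alpha = 0.05)
  sig <- res$tests[res$tests$significant, c("chromA", "chromB")]
  expect_setequal(paste(sig$chromA, sig$chromB),
                  paste(sim$truth$chromA, sim$truth$chromB))
  # lenient alpha only grows the significant set
  res2 <- run_synteny(sim$hits, sim$chromA, sim$chromB, alpha = 0.2)
  expect_true(all(res$tests$significant[order(res$tests$chromA,
                                              res$tests$chromB)] <=
                    res2$tests$significant[order(res2$tests$chromA,
                                                 res2$tests$chromB)]))
  expect_error(run_synteny(sim$hits[0, ], sim$chromA, sim$chromB), "empty")
})

test_that("synteny reports write tested, significant and ribbon tables", {
  sim <- simulate_orthologs(n_chrom_A = 4, n_chrom_B = 4, n_pairs = 200,
                            noise_fraction = 0.1, seed = 21)
  dir <- withr::local_tempdir()
  res <- run_synteny(sim$hits, sim$chromA, sim$chromB, outdir = dir)
  expect_true(all(file.exists(res$files)))
  rt <- read.delim(res$files["tests"])
  expect_equal(nrow(rt), nrow(res$tests))
})
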