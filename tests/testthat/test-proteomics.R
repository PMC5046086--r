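make_spc <- function(counts_by_sample, groups) {
  counts <- do.call(cbind, counts_by_sample)
  rownames(counts) <- sprintf("P%d", seq_len(nrow(counts)))
  colnames(counts) <- names(counts_by_sample)
  spc_table(counts, groups)
}

test_that("percentile ranks span 0-100 with average-rank ties", {
  tab <- make_spc(list(m1 = c(1L, 3L, 5L, 7L, 9L)), "matrix")
  expect_equal(unname(percentile_ranks(tab)[, 1]), c(0, 25, 50, 75, 100))
  # top two tied among 5: both at 87.5
  tab2 <- make_spc(list(m1 = c(1L, 3L, 5L, 9L, 9L)), "matrix")
  expect_equal(unname(percentile_ranks(tab2)[, 1]), c(0, 25, 50, 87.5, 87.5))
})

test_that("undetected proteins get percentile 0 and a not-detected mark", {
  tab <- make_spc(list(m1 = c(10L, 4L, 2L), f1 = c(0L, 5L, 1L)),
                  c("matrix", "fluid"))
  r <- percentile_ranks(tab)
  expect_equal(unname(r["P1", ]), c(100, 0))
  expect_false(attr(r, "detected")["P1", "f1"])
  expect_true(attr(r, "detected")["P1", "m1"])
})

test_that("percentiles are monotone in SpC and order-invariant", {
  set.seed(31)
  counts <- matrix(rpois(40, 20), ncol = 2,
                   dimnames = list(sprintf("P%d", 1:20), c("m1", "f1")))
  tab <- spc_table(counts, c("matrix", "fluid"))
  r <- percentile_ranks(tab)
  for (j in 1:2) {
    ord <- order(counts[, j])
    expect_true(all(diff(r[ord, j]) >= 0))
  }
  perm <- sample(nrow(counts))
  tabp <- spc_table(counts[perm, ], c("matrix", "fluid"))
  expect_equal(percentile_ranks(tabp)[rownames(counts), ],
               r[, , drop = FALSE], ignore_attr = TRUE)
})

test_that("enrichment summary computes group means, SEMs and differences", {
  tab <- make_spc(list(m1 = c(8L, 1L), m2 = c(8L, 1L), m3 = c(8L, 1L),
                       f1 = c(1L, 6L), f2 = c(3L, 4L)),
                  c(rep("matrix", 3), rep("fluid", 2)))
  r <- percentile_ranks(tab)
  es <- enrichment_summary(r)
  # identical ranks across matrix replicates: SEM 0
  expect_equal(es$sem_rank_matrix, c(0, 0))
  expect_equal(es$rank_difference,
               es$mean_rank_matrix - es$mean_rank_fluid)
  expect_true(all(diff(es$rank_difference) <= 0))  # sorted descending

  # SEM equals the two-pass variance formula oracle
  ranks <- matrix(c(0, 50, 100, 10, 20, 30), nrow = 1)
  colnames(ranks) <- c("m1", "m2", "m3", "f1", "f2", "f3")
  rownames(ranks) <- "P1"
  es2 <- enrichment_summary(ranks, groups = c(rep("matrix", 3), rep("fluid", 3)))
  v <- c(0, 50, 100)
  expect_equal(es2$sem_rank_matrix,
               sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / sqrt(length(v)))
  # n = 1 group: SEM reported missing
  es3 <- enrichment_summary(ranks[, c(1, 4), drop = FALSE],
                            groups = c("matrix", "fluid"))
  expect_true(is.na(es3$sem_rank_matrix))
})

test_that("pI reproduces closed forms and the dense-grid oracle", {
  # no ionizable side chains: midpoint of the terminal pKas (EMBOSS 8.6, 3.6)
  expect_equal(compute_pI("GGGG"), 6.10, tolerance = 1e-3)
  d8 <- compute_pI(strrep("D", 8))
  k8 <- compute_pI(strrep("K", 8))
  expect_equal(d8, grid_pi_oracle(strrep("D", 8)), tolerance = 0.001)
  expect_equal(k8, grid_pi_oracle(strrep("K", 8)), tolerance = 0.001)
  expect_lt(d8, 4); expect_gt(k8, 9)
  # alternative pKa sets shift the answer but stay near the oracle
  expect_equal(compute_pI("ACDKR", pka_set = "Lehninger"),
               grid_pi_oracle("ACDKR", pka_set = "Lehninger"),
               tolerance = 0.001)
})

test_that("pI agrees with the grid oracle across random sequences", {
  set.seed(41)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:200) {
    s <- paste(sample(aa, sample(10:500, 1), replace = TRUE), collapse = "")
    expect_lt(abs(compute_pI(s) - grid_pi_oracle(s, step = 1e-3)), 0.01)
  }
})

test_that("net charge decreases strictly in pH (unique pI root)", {
  set.seed(43)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    s <- paste(sample(aa, 50, replace = TRUE), collapse = "")
    z <- protein_charge(s, seq(0, 14, by = 0.05))
    expect_true(all(diff(z) < 0))
  }
})

test_that("acidic region scan finds planted glutamate stretches", {
  plants <- data.frame(seq = 1, start = 100, len = 39, residue = "E")
  seqs <- simulate_sequences(n = 2, length = 300, planted = plants, seed = 17)
  hits <- acidic_region_scan(seqs[[1]])
  expect_equal(nrow(hits), 1)
  expect_lte(hits$start, 100)
  expect_gte(hits$end, 138)
  expect_lt(hits$window_pI, 4)
  expect_gt(hits$composition, 0.3)
  # unplanted neutral-background sequence: nothing below pI 4
  expect_equal(nrow(acidic_region_scan(seqs[[2]])), 0)
  # all-glycine: no acidic residues at all
  expect_equal(nrow(acidic_region_scan(strrep("G", 80))), 0)
  expect_error(acidic_region_scan("SHORT", window = 39), "longer than")
})

test_that("region boundaries agree with an exhaustive window oracle", {
  plants <- data.frame(seq = 1, start = 60, len = 25, residue = "D")
  s <- simulate_sequences(n = 1, length = 160, planted = plants, seed = 23)[[1]]
  win <- 20; thr <- 4
  hits <- acidic_region_scan(s, window = win, pI_threshold = thr)
  qual <- vapply(seq_len(nchar(s) - win + 1), function(i) {
    p <- grid_pi_oracle(substr(s, i, i + win - 1), include_termini = FALSE,
                        step = 1e-3)
    !is.na(p) && p < thr
  }, TRUE)
  runs <- rle(qual)
  stops <- cumsum(runs$lengths); starts <- stops - runs$lengths + 1
  expect_equal(hits$start, starts[runs$values])
  expect_equal(hits$end, stops[runs$values] + win - 1)
})

test_that("acidic regions reflect under sequence reversal", {
  plants <- data.frame(seq = 1, start = 40, len = 39, residue = "E")
  s <- simulate_sequences(n = 1, length = 150, planted = plants, seed = 29)[[1]]
  fwd <- acidic_region_scan(s)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  bwd <- acidic_region_scan(rev_s)
  L <- nchar(s)
  expect_equal(fwd$start, sort(L - bwd$end + 1))
  expect_equal(fwd$end, sort(L - bwd$start + 1))
})

test_that("acidic protein counting uses a strict pI cutoff", {
  expect_equal(count_acidic_proteins(numeric(0)), 0)
  expect_equal(count_acidic_proteins(c(4.9, 5.0, 5.1)), 1)
  seqs <- c(strrep("D", 30), strrep("K", 30),
            paste(rep("G", 30), collapse = ""))
  expect_equal(count_acidic_proteins(seqs), 1)
})
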