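test_that("identical and proportional libraries get unit factors and equal CPM", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  res <- rle_cpm(m)
  expect_equal(unname(res$norm_factors), c(1, 1))
  expect_equal(res$cpm[, "A"], res$cpm[, "B"])

  tripled <- m
  tripled[, "B"] <- 3 * m[, "A"]
  res3 <- rle_cpm(tripled)
  expect_equal(res3$cpm[, "A"], res3$cpm[, "B"])
})

test_that("factors match a hand evaluation of the median-of-ratios formula", {
  counts <- matrix(c(100, 50, 10, 200, 5,
                     200, 100, 40, 400, 10,
                     300, 150, 30, 660, 15), nrow = 5,
                   dimnames = list(paste0("g", 1:5), c("s1", "s2", "s3")))
  res <- rle_cpm(counts)
  lib <- colSums(counts)
  prop <- sweep(counts, 2, lib, "/")
  ref <- apply(prop, 1, function(r) exp(mean(log(r))))
  f_raw <- vapply(1:3, function(j) median(prop[, j] / ref), 0)
  f <- f_raw / exp(mean(log(f_raw)))
  expect_equal(unname(res$norm_factors), f)
  expect_equal(res$cpm, sweep(counts, 2, lib * f, "/") * 1e6)
  expect_equal(exp(mean(log(res$norm_factors))), 1)
})

test_that("rle_cpm agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(71)
  counts <- matrix(rnbinom(500 * 6, mu = 50, size = 5), nrow = 500,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   paste0("s", 1:6)))
  counts[1:20, 1] <- 0  # zeros excluded from the reference only
  res <- rle_cpm(counts)
  dge <- edgeR::DGEList(counts)
  dge <- edgeR::calcNormFactors(dge, method = "RLE")
  expect_equal(unname(res$norm_factors), unname(dge$samples$norm.factors),
               tolerance = 1e-10)
  expect_equal(res$cpm, edgeR::cpm(dge, normalized.lib.sizes = TRUE),
               tolerance = 1e-10)
})

test_that("per-sample scaling leaves every CPM column unchanged", {
  set.seed(72)
  counts <- matrix(rnbinom(200 * 5, mu = 40, size = 5) + 1, nrow = 200,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   paste0("s", 1:5)))
  base <- rle_cpm(counts)
  scaled <- counts
  scaled[, 3] <- counts[, 3] * 7
  res <- rle_cpm(scaled)
  expect_equal(res$cpm, base$cpm, tolerance = 1e-12)
})

test_that("degenerate count matrices are rejected", {
  m <- matrix(c(0, 5, 3, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(rle_cpm(m), "no gene has positive counts")
  z <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(rle_cpm(z), "zero library")
  expect_error(rle_cpm(matrix(1:4, 4, 1)), ">= 2 samples")
})

test_that("median split by gene delegates to the cohort rule", {
  cpm <- list(cpm = matrix(c(1, 2, 3, 4), nrow = 1,
                           dimnames = list("GRN", paste0("s", 1:4))))
  class(cpm) <- "cpm_matrix"
  d <- median_split_by_gene(cpm, "GRN")
  expect_identical(attr(d, "n_high"), 2L)
  expect_identical(d$id[d$label == "high"], c("s3", "s4"))
  expect_error(median_split_by_gene(cpm, "NOPE"), "not in matrix")
  flat <- cpm
  flat$cpm[1, ] <- 5
  expect_error(median_split_by_gene(flat, "GRN"), "degenerate")
})

test_that("64 distinct stroma samples split 32/32", {
  sim <- simulate_counts(n_genes = 300, n_subjects = 64, seed = 73)
  cpm <- rle_cpm(sim$counts)
  stroma <- sim$annotation$sample[sim$annotation$compartment == "stroma"]
  d <- median_split_by_gene(cpm, "GRN", samples = stroma)
  expect_identical(attr(d, "n_high"), 32L)
  expect_identical(attr(d, "n_low"), 32L)
})

test_that("median split recovers bimodal generating components", {
  # 4-fold separated stroma components should be recovered for >= 95% of
  # samples by the median split
  agree <- vapply(1:5, function(s) {
    sim <- simulate_counts(n_genes = 400, n_subjects = 64, strat_fold = 4,
                           seed = 100 + s)
    cpm <- rle_cpm(sim$counts)
    stroma <- sim$annotation$sample[sim$annotation$compartment == "stroma"]
    d <- median_split_by_gene(cpm, "GRN", samples = stroma)
    lab <- d$label[match(paste0(sim$truth$subject, "_str"), d$id)]
    mean(lab == sim$truth$stroma_component)
  }, 0)
  expect_gte(mean(agree), 0.95)
})

test_that("paired Spearman handles perfect monotone pairs and drops incompletes", {
  cpm <- list(cpm = matrix(c(1, 2, 3, 2, 4, 6, 99), nrow = 1,
                           dimnames = list("GRN",
                                           c("a_e", "b_e", "c_e",
                                             "a_s", "b_s", "c_s", "d_e"))))
  class(cpm) <- "cpm_matrix"
  ann <- data.frame(
    sample = c("a_e", "b_e", "c_e", "a_s", "b_s", "c_s", "d_e"),
    subject = c("a", "b", "c", "a", "b", "c", "d"),
    compartment = c(rep("epithelium", 3), rep("stroma", 3), "epithelium"))
  res <- paired_spearman(cpm, "GRN", ann)
  expect_equal(res$rho, 1)
  expect_identical(res$n_pairs, 3L)
  expect_identical(res$dropped_subjects, "d")

  anti <- cpm
  anti$cpm[1, 4:6] <- c(6, 4, 2)
  expect_equal(paired_spearman(anti, "GRN", ann)$rho, -1)
})

test_that("paired Spearman matches direct midrank arithmetic with ties", {
  e <- c(1.2, 3.4, 3.4, 0.5, 2.2, 7.7, 5.1, 5.1, 0.1, 4.4)
  s <- c(2.0, 1.1, 6.3, 0.9, 2.2, 2.2, 8.8, 0.3, 4.1, 4.1)
  n <- length(e)
  cpm <- list(cpm = matrix(2^c(e, s) - 1, nrow = 1,
                           dimnames = list("GRN",
                                           c(paste0("p", 1:n, "_e"),
                                             paste0("p", 1:n, "_s")))))
  class(cpm) <- "cpm_matrix"
  ann <- data.frame(sample = colnames(cpm$cpm),
                    subject = rep(paste0("p", 1:n), 2),
                    compartment = rep(c("epithelium", "stroma"), each = n))
  res <- paired_spearman(cpm, "GRN", ann, pseudocount = 1)
  want <- spearman_direct(e, s)
  expect_equal(res$rho, want$rho, tolerance = 1e-9)
  expect_equal(res$p_two_tailed, want$p, tolerance = 1e-9)
  # rank-based: invariant to the pseudocount
  res2 <- paired_spearman(cpm, "GRN", ann, pseudocount = 10)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)
})

test_that("the ranking statistic follows -ln(p) * sign(log2FC)", {
  de <- data.frame(gene = c("up", "dn", "flat"),
                   log2FC = c(1.5, -2, 0.7),
                   pvalue = c(0.01, 0.01, 1))
  r <- rank_statistic(de)
  expect_equal(r$rank_stat[r$gene == "up"], -log(0.01))
  expect_equal(r$rank_stat[r$gene == "dn"], log(0.01))
  expect_equal(r$rank_stat[r$gene == "dn"], -4.6052, tolerance = 1e-4)
  expect_equal(r$rank_stat[r$gene == "flat"], 0)
  expect_error(rank_statistic(transform(de, pvalue = c(0, 0.5, 1))),
               "floor")
})

test_that("ranking order matches an independent re-sort on random records", {
  set.seed(74)
  de <- data.frame(gene = sprintf("g%03d", sample(100)),
                   log2FC = rnorm(100),
                   pvalue = runif(100, 1e-6, 1))
  r <- rank_statistic(de)
  stat <- -log(de$pvalue) * sign(de$log2FC)
  want <- de$gene[order(-stat, de$gene)]
  expect_identical(r$gene, want)
  expect_true(all(diff(r$rank_stat) <= 0))
  # sign invariant: rank_stat sign equals log2FC sign when p < 1
  strict <- de$pvalue < 1
  expect_identical(sign(r$rank_stat[match(de$gene[strict], r$gene)]),
                   sign(de$log2FC[strict]))
})

test_that("counts, annotations, DE tables and rankings round-trip through disk", {
  sim <- simulate_counts(n_genes = 50, n_subjects = 4, seed = 75)
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "counts.tsv")
  write.table(data.frame(gene = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts_tsv(cpath)
  expect_equal(back, sim$counts, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(sim$counts))

  apath <- file.path(dir, "annot.csv")
  write.csv(sim$annotation, apath, row.names = FALSE)
  expect_equal(read_annotation_csv(apath), sim$annotation)

  de <- data.frame(gene = c("b", "a"), log2FC = c(1, -1),
                   pvalue = c(0.2, 0.04))
  r <- rank_statistic(de)
  rpath <- file.path(dir, "out.rnk")
  write_rnk(r, rpath)
  reread <- read.delim(rpath, header = FALSE)
  expect_identical(as.character(reread$V1), r$gene)
  expect_equal(reread$V2, r$rank_stat, tolerance = 1e-6)
})
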