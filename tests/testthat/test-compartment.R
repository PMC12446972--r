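compMeta <- function(n_each = 4) {
  data.frame(sample_id = paste0("S", seq_len(3 * n_each)),
             compartment = rep(c("NAT", "PC", "TUMOR"), each = n_each))
}

test_that("PCA recovers structure and matches an eigen oracle", {
  # rank-1 matrix: one component explains everything
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  m <- outer(v, u)
  dimnames(m) <- list(paste0("P", 1:3), paste0("S", 1:4))
  res <- quantPCA(QuantMatrix(m, "protein"))
  expect_equal(res$varianceExplained[1], 100, tolerance = 1e-9)
  # 3x3 oracle: scores from the eigendecomposition of the covariance
  set.seed(51)
  m2 <- matrix(rnorm(9, 20), 3, 3,
               dimnames = list(paste0("P", 1:3), paste0("S", 1:3)))
  res2 <- quantPCA(QuantMatrix(m2, "protein"))
  x <- scale(t(m2), scale = FALSE)
  ev <- eigen(x %*% t(x))
  expect_equal(sort(res2$varianceExplained, decreasing = TRUE),
               (100 * ev$values / sum(ev$values))[
                 seq_along(res2$varianceExplained)], tolerance = 1e-8)
  expect_equal(abs(res2$scores), abs(ev$vectors[, seq_len(ncol(res2$scores)),
                                                drop = FALSE] %*%
                                       diag(sqrt(ev$values[seq_len(
                                         ncol(res2$scores))]))),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("PCA reconstruction and score duplication behave", {
  set.seed(52)
  m <- matrix(rnorm(20 * 8, 20, 2), 20, 8,
              dimnames = list(paste0("P", 1:20), paste0("S", 1:8)))
  res <- quantPCA(QuantMatrix(m, "protein"))
  expect_true(all(diff(res$varianceExplained) <= 1e-9))
  recon <- res$scores %*% t(res$loadings)
  centered <- scale(t(m), scale = FALSE)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicated samples get identical scores
  m2 <- cbind(m, S9 = m[, 1])
  res2 <- quantPCA(QuantMatrix(m2, "protein"))
  expect_equal(res2$scores["S9", ], res2$scores["S1", ], tolerance = 1e-9)
  expect_error(quantPCA(qmat(matrix(c(1, NA, 2, 3), 2))), "missing")
})

test_that("monotone trends are called per the margin rule", {
  md <- compMeta(4)
  inc <- rep(c(18, 19, 20), each = 4)  # clear increasing trend
  dec <- rep(c(20, 19, 18), each = 4)
  flat <- rep(20, 12)
  set.seed(53)
  m <- rbind(inc + rnorm(12, 0, 0.05), dec + rnorm(12, 0, 0.05), flat)
  dimnames(m) <- list(c("INC", "DEC", "FLAT"), md$sample_id)
  res <- trendClusters(QuantMatrix(m, "protein", sampleData = md))
  expect_equal(res$cluster, c("increasing", "decreasing", "none"))
  expect_true(all(res$effect_size[1:2] > 0.5))
})

test_that("swapping NAT and TUMOR labels mirrors the trend calls", {
  set.seed(54)
  md <- compMeta(5)
  m <- matrix(rnorm(50 * 15, 20, 1), 50, 15,
              dimnames = list(paste0("P", 1:50), md$sample_id))
  m[1:10, md$compartment == "TUMOR"] <- m[1:10, md$compartment == "TUMOR"] + 2
  m[1:10, md$compartment == "PC"] <- m[1:10, md$compartment == "PC"] + 1
  r1 <- trendClusters(QuantMatrix(m, "protein", sampleData = md))
  md2 <- md
  md2$compartment <- c(NAT = "TUMOR", PC = "PC",
                       TUMOR = "NAT")[md$compartment]
  r2 <- trendClusters(QuantMatrix(m, "protein", sampleData = md2))
  swap <- c(increasing = "decreasing", decreasing = "increasing",
            none = "none")
  expect_equal(r2$cluster, unname(swap[r1$cluster]))
})

test_that("planted monotone panels are recovered among null features", {
  set.seed(55)
  md <- compMeta(30)  # cohort-scale groups keep the margin rule calibrated
  n <- 500
  ns <- nrow(md)
  m <- matrix(rnorm(n * ns, 20, 1), n, ns,
              dimnames = list(paste0("P", 1:n), md$sample_id))
  # plant 50 increasing and 50 decreasing features with a 1.5 sd span
  for (i in 1:50) {
    m[i, ] <- m[i, ] + rep(c(0, 0.75, 1.5), each = 30)
    m[i + 50, ] <- m[i + 50, ] + rep(c(1.5, 0.75, 0), each = 30)
  }
  res <- trendClusters(QuantMatrix(m, "protein", sampleData = md))
  expect_gte(mean(res$cluster[1:50] == "increasing"), 0.9)
  expect_gte(mean(res$cluster[51:100] == "decreasing"), 0.9)
  expect_lt(mean(res$cluster[101:n] != "none"), 0.05)
})

test_that("size correlation is exact for linear features and affine-stable", {
  d <- c(12, 20, 28, 35, 44, 52, 60, 71)
  m <- rbind(20 + 0.05 * d, 20 - 0.03 * d, rep(20, 8))
  dimnames(m) <- list(c("POS", "NEG", "CONST"), paste0("S", 1:8))
  res <- sizeCorrelation(QuantMatrix(m, "protein"), d)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_equal(res$r[2], -1, tolerance = 1e-12)
  expect_equal(res$direction[1:2], c("positive", "negative"))
  expect_true(res$constant[3])
  expect_equal(res$direction[3], "ns")
  # affine rescaling of diameters (mm -> cm + offset) changes nothing
  set.seed(56)
  m2 <- matrix(rnorm(40, 20), 5, 8,
               dimnames = list(paste0("P", 1:5), paste0("S", 1:8)))
  r1 <- sizeCorrelation(QuantMatrix(m2, "protein"), d)
  r2 <- sizeCorrelation(QuantMatrix(m2, "protein"), d / 10 + 3)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  # positive and negative sets disjoint by construction
  expect_length(intersect(res$feature_id[res$direction == "positive"],
                          res$feature_id[res$direction == "negative"]), 0)
})

test_that("marker correlations are computed within compartments", {
  set.seed(57)
  md <- compMeta(20)
  genes <- c("PCNA", "MCM2", "MCM3", "OTHER")
  m <- matrix(rnorm(4 * 60, 20, 1), 4, 60,
              dimnames = list(genes, md$sample_id))
  tum <- md$compartment == "TUMOR"
  shared <- rnorm(sum(tum))
  m["PCNA", tum] <- m["PCNA", tum] + shared
  m["MCM2", tum] <- m["MCM2", tum] + shared
  q <- QuantMatrix(m, "protein", sampleData = md,
                   rowData = data.frame(gene = genes))
  res <- markerCorrelation(q, "PCNA", c("PCNA", "MCM2", "MCM3"))
  self <- res[res$gene == "PCNA", ]
  expect_true(all(abs(self$r - 1) < 1e-12))
  r_tum <- res$r[res$gene == "MCM2" & res$compartment == "TUMOR"]
  r_nat <- res$r[res$gene == "MCM2" & res$compartment == "NAT"]
  expect_gt(r_tum, r_nat)
  expect_gt(r_tum, 0.3)
  expect_warning(markerCorrelation(q, "PCNA", c("MCM2", "NOPE")),
                 "not found")
  expect_error(markerCorrelation(q, "NOPE", "MCM2"), "anchor")
})

test_that("peptide-protein concordance flags discordant peptides", {
  protDA <- data.frame(feature_id = c("A", "B", "C"),
                       log2fc = c(1, -1, 0.05),
                       adj_p = c(0.01, 0.01, 0.8))
  pepDA <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                      log2fc = c(1, 1, -1, 0.1),
                      adj_p = c(0.01, 0.01, 0.01, 0.9))
  mapping <- data.frame(peptide_id = c("p1", "p2", "p3", "p4"),
                        protein_id = c("A", "B", "C", "A"))
  res <- peptideProteinConcordance(pepDA, protDA, mapping)
  # p2 contradicts its protein's sign; p3 changes while C does not
  expect_setequal(res$discordant$peptide_id, c("p2", "p3"))
  expect_equal(res$discordant$reason[res$discordant$peptide_id == "p2"],
               "opposite_sign")
  expect_equal(res$discordant$reason[res$discordant$peptide_id == "p3"],
               "protein_ns")
  # identical fold changes give r = 1 and nothing discordant
  pep2 <- data.frame(feature_id = c("p1", "p2"), log2fc = c(1, -1),
                     adj_p = c(0.01, 0.01))
  map2 <- data.frame(peptide_id = c("p1", "p2"), protein_id = c("A", "B"))
  res2 <- peptideProteinConcordance(pep2, protDA, map2)
  expect_equal(res2$r, 1)
  expect_equal(nrow(res2$discordant), 0L)
  expect_error(peptideProteinConcordance(
    pepDA, protDA, data.frame(peptide_id = "x", protein_id = "y")),
    "no peptide-protein pairs")
})
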