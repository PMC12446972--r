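# small annotated peptide fixture on the toy protein MKLVRAGDSTKNNFW
fixtureAnnotated <- function() {
  db <- toyProteins()
  peps <- data.frame(
    stripped_sequence = c("AGDSTK", "GDSTK", "LVRAGDSTK", "AGDST", "MKLVR"),
    protein_group = "P0TEST", gene = "G0",
    proteotypic = TRUE, stringsAsFactors = FALSE)
  intens <- matrix(100, nrow = 5, ncol = 4,
                   dimnames = list(NULL, paste0("S", 1:4)))
  pt <- structure(list(peptides = peps, intensities = intens),
                  class = "PeptideTable")
  list(db = db, pt = pt, ann = classifyPeptides(peps, db))
}

test_that("semi fractions follow their definition", {
  fx <- fixtureAnnotated()
  # classified: AGDSTK full, GDSTK semi_N, LVRAGDSTK full, AGDST semi_C,
  # MKLVR terminal (excluded from both sides)
  fr <- semiFractionPerSample(fx$ann, fx$pt)
  expect_equal(fr$n_full, rep(2L, 4))
  expect_equal(fr$n_semi, rep(2L, 4))
  expect_equal(fr$fraction_count, rep(0.5, 4))
  expect_equal(fr$fraction_intensity, rep(0.5, 4))
  # missing intensities leave the sample's fraction on present peptides only
  fx$pt$intensities[2, "S1"] <- NA  # GDSTK absent in S1
  fx$pt$intensities[4, "S1"] <- NA  # AGDST absent in S1
  fr2 <- semiFractionPerSample(fx$ann, fx$pt)
  expect_equal(fr2$fraction_count[fr2$sample_id == "S1"], 0)
  expect_equal(fr2$fraction_intensity[fr2$sample_id == "S1"], 0)
})

test_that("intensity fraction weighs by raw intensity, not by count", {
  fx <- fixtureAnnotated()
  fx$pt$intensities[2, ] <- 300  # semi peptide 3x brighter
  fx$pt$intensities[4, ] <- NA   # drop the other semi peptide
  fr <- semiFractionPerSample(fx$ann, fx$pt)
  expect_equal(fr$fraction_count, rep(1 / 3, 4))
  expect_equal(fr$fraction_intensity, rep(300 / 500, 4))
})

test_that("identical fractions across groups give null p-values", {
  values <- data.frame(sample_id = paste0("S", 1:12),
                       fraction_intensity = rep(0.2, 12))
  md <- data.frame(sample_id = paste0("S", 1:12),
                   compartment = rep(c("NAT", "PC", "TUMOR"), each = 4))
  res <- groupCompareFractions(values, md)
  dunn <- res$pairwise[res$pairwise$method == "dunn", ]
  expect_true(all(dunn$adj_p == 1))
  # constant data leaves the parametric fit numerically degenerate
  # (0/0 mean squares), so only require the Tukey p to be clearly null
  tukey <- res$pairwise[res$pairwise$method == "tukey", ]
  expect_true(all(is.na(tukey$p) | tukey$p > 0.5))
})

test_that("pairwise tests are symmetric under group relabeling", {
  set.seed(3)
  values <- data.frame(sample_id = paste0("S", 1:15),
                       fraction_intensity = runif(15))
  md <- data.frame(sample_id = paste0("S", 1:15),
                   compartment = rep(c("NAT", "PC", "TUMOR"), each = 5))
  res1 <- groupCompareFractions(values, md)
  md2 <- md
  md2$compartment <- c(NAT = "TUMOR", PC = "PC",
                       TUMOR = "NAT")[md$compartment]
  res2 <- groupCompareFractions(values, md2)
  d1 <- res1$pairwise[res1$pairwise$method == "dunn", ]
  d2 <- res2$pairwise[res2$pairwise$method == "dunn", ]
  expect_equal(sort(d1$p), sort(d2$p))
  expect_equal(res1$omnibus$p, res2$omnibus$p)
})

test_that("rank-based pairwise test holds its nominal size under the null", {
  set.seed(101)
  n_sim <- 2000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(20)
    g <- factor(rep(c("NAT", "TUMOR"), each = 10), levels =
                  c("NAT", "PC", "TUMOR"))
    d <- proteocaps:::.dunnTest(x, g)
    rej[i] <- d$p[1] <= 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("per-gene semi counts are distinct present sequences", {
  fx <- fixtureAnnotated()
  # duplicate row of the same semi sequence must not double-count
  pt <- fx$pt
  pt$peptides <- rbind(pt$peptides, pt$peptides[2, ])
  pt$intensities <- rbind(pt$intensities, pt$intensities[2, ])
  ann <- classifyPeptides(pt$peptides, fx$db)
  counts <- semiCountsPerProtein(ann, pt, "G0")
  expect_equal(unique(counts$count), 2L)  # GDSTK + AGDST, deduplicated
  pt$intensities[c(2, 4, 6), "S1"] <- NA
  counts2 <- semiCountsPerProtein(suppressWarnings(
    classifyPeptides(pt$peptides, fx$db)), pt, "G0")
  expect_equal(counts2$count[counts2$sample_id == "S1"], 0L)
  expect_warning(semiCountsPerProtein(ann, pt, c("G0", "NOGENE")),
                 "unknown gene")
})

test_that("family shares are arithmetic on distinct semi peptides", {
  db <- data.frame(
    accession = c("A", "B"),
    gene = c("COLX", "OTHERG"),
    sequence = c("MKLVRAGDSTKNNFWAAACDEFGHKTTTR",
                 "MKLVRWWGDSTWKNNFQQQCDEFGHKTTTR"),
    stringsAsFactors = FALSE)
  # three semi peptides from COLX, one from OTHERG
  peps <- data.frame(
    stripped_sequence = c("GDSTKNNFWAAACDEFGHK", "DSTKNNFWAAACDEFGHK",
                          "STKNNFWAAACDEFGHK", "WGDSTWKNNFQQQCDEFGHK"),
    protein_group = c("A", "A", "A", "B"),
    proteotypic = TRUE, stringsAsFactors = FALSE)
  ann <- classifyPeptides(peps, db)
  expect_true(all(ann$spec_class == "semi_N"))
  share <- proteinFamilyShare(ann, db, c(COLX = "collagen"))
  expect_equal(share$share[share$family == "collagen"], 0.75)
  expect_equal(sum(share$share), 1, tolerance = 1e-12)
})

test_that("motif matrix highlights a planted P1' preference", {
  db <- toyProteins()
  ev <- data.frame(
    peptide = "X", accession = "P0TEST", position = 6L, side = "peptide_N",
    window = rep("AAAALAAA", 50), stringsAsFactors = FALSE)
  m <- motifEnrichment(ev, db)
  expect_equal(dim(m), c(20L, 8L))
  expect_equal(colnames(m)[5], "P1'")
  expect_equal(rownames(m)[which.max(m[, "P1'"])], "L")
  expect_true(all(is.finite(m)))
})

test_that("motif matrix is order-invariant and stable under doubling", {
  set.seed(5)
  db <- data.frame(accession = "R", gene = "R",
                   sequence = randomProtein(400), stringsAsFactors = FALSE)
  win <- vapply(sample(5:390, 120, replace = TRUE), function(p)
    proteocaps:::.cleavageWindow(db$sequence, p), "")
  ev <- data.frame(peptide = "X", accession = "R", position = 1L,
                   side = "peptide_N", window = win,
                   stringsAsFactors = FALSE)
  m1 <- motifEnrichment(ev, db)
  m2 <- motifEnrichment(ev[sample(nrow(ev)), ], db)
  expect_equal(m1, m2, ignore_attr = TRUE)
  # doubling every event only moves entries through the pseudocount terms:
  # |log2((2c+1)/(2T+20)) - log2((c+1)/(T+20))| is largest for c = 0 and
  # always below 1; well-populated cells barely move
  m3 <- motifEnrichment(rbind(ev, ev), db)
  expect_lt(max(abs(m3 - m1)), 1)
  expect_lt(median(abs(m3 - m1)), 0.1)
  expect_error(motifEnrichment(ev[0, ], db), "zero")
})

test_that("tryptic-sites background discounts the K/R signal at P1", {
  set.seed(6)
  db <- data.frame(accession = "R", gene = "R",
                   sequence = randomProtein(600), stringsAsFactors = FALSE)
  chars <- strsplit(db$sequence, "")[[1]]
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites > 4 & sites < 590]
  ev <- data.frame(peptide = "X", accession = "R", position = sites,
                   side = "peptide_C",
                   window = vapply(sites, function(p)
                     proteocaps:::.cleavageWindow(db$sequence, p), ""),
                   stringsAsFactors = FALSE)
  m_prot <- motifEnrichment(ev, db, background = "proteome")
  m_tryp <- motifEnrichment(ev, db, background = "tryptic_sites")
  # events ARE tryptic sites: strong K/R signal at P1 against the proteome,
  # none against the tryptic-site background
  expect_gt(max(m_prot[c("K", "R"), "P1"]), 1)
  expect_lt(max(abs(m_tryp[, "P1"])), 0.2)
})
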