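# a scaled-down configuration keeps the module tests quick; the full-size
# defaults are exercised by the acceptance suite
smallConfig <- function(...) {
  simConfig(n_proteins = 150, n_cleavage_events = 300, ...)
}

test_that("the cohort generator is deterministic under (config, seed)", {
  c1 <- simulateCohort(smallConfig(), seed = 9)
  c2 <- simulateCohort(smallConfig(), seed = 9)
  expect_identical(c1$proteins, c2$proteins)
  expect_identical(c1$peptideTable$intensities, c2$peptideTable$intensities)
  expect_identical(c1$metadata, c2$metadata)
  # a different seed changes the values but not the sample dimension
  c3 <- simulateCohort(smallConfig(), seed = 10)
  expect_equal(ncol(c3$peptideTable$intensities),
               ncol(c1$peptideTable$intensities))
  expect_false(identical(c1$peptideTable$intensities,
                         c3$peptideTable$intensities))
})

test_that("the sample sheet reproduces the cohort structure", {
  ch <- simulateCohort(smallConfig(), seed = 1)
  md <- ch$metadata
  expect_equal(unname(table(md$compartment)[c("NAT", "PC", "TUMOR")]),
               c(31L, 45L, 54L), ignore_attr = TRUE)
  expect_equal(length(unique(md$patient_id)), 34L)
  expect_false(anyDuplicated(md$sample_id) > 0)
  # every PC sample inherits its matched tumor lesion's diameter
  tum <- md[md$compartment == "TUMOR", ]
  pc <- md[md$compartment == "PC", ]
  key <- paste(tum$patient_id, tum$lesion_index)
  expect_true(all(paste(pc$patient_id, pc$lesion_index) %in% key))
  expect_equal(pc$tumor_diameter,
               tum$tumor_diameter[match(paste(pc$patient_id,
                                              pc$lesion_index), key)])
  expect_true(all(is.na(md$tumor_diameter[md$compartment == "NAT"])))
  expect_true(all(md$lesion_index >= 1))
  # metachronous lesions exist and stay within the configured patient count
  expect_gt(sum(md$compartment == "TUMOR" & md$lesion_index > 1), 0)
})

test_that("the generated proteome honours composition constraints", {
  set.seed(2)
  prot <- makeProteome(simConfig(n_proteins = 200))
  expect_equal(nrow(prot), 200L)
  expect_false(anyDuplicated(prot$accession) > 0)
  allres <- strsplit(paste(prot$sequence, collapse = ""), "")[[1]]
  expect_true(all(allres %in% AA20))
  kr <- mean(allres %in% c("K", "R"))
  expect_gt(kr, 0.09)
  expect_lt(kr, 0.13)
  lens <- nchar(prot$sequence)
  expect_true(all(lens >= 150 & lens <= 1000))
})

test_that("digestion equals brute-force enumeration", {
  set.seed(3)
  for (i in 1:5) {
    sq <- randomProtein(sample(100:250, 1))
    mine <- sort(digestProtein(sq)$peptide)
    oracle <- sort(bruteDigest(sq))
    expect_equal(mine, oracle)
  }
  # protein without cleavage sites: the whole chain iff short enough
  expect_equal(digestProtein(strrep("A", 20))$peptide, strrep("A", 20))
  expect_equal(nrow(digestProtein(strrep("A", 40))), 0L)
})

test_that("digest products classify as fully tryptic or terminal", {
  set.seed(4)
  sq <- randomProtein(300)
  db <- data.frame(accession = "X", gene = "X", sequence = sq,
                   stringsAsFactors = FALSE)
  d <- digestProtein(sq)
  peps <- data.frame(stripped_sequence = d$peptide, protein_group = "X",
                     proteotypic = TRUE, stringsAsFactors = FALSE)
  ann <- classifyPeptides(peps, db)
  expect_true(all(ann$spec_class == "full" | ann$terminal_excluded))
})

test_that("sampled cleavage products respect the P1' preference", {
  set.seed(5)
  sq <- randomProtein(600)
  d <- digestProtein(sq)
  w <- setNames(rep(0, 20), AA20)
  w["L"] <- 1  # all probability mass on leucine
  sel <- applyEndogenousCleavage(sq, d, 40, w)
  expect_true(all(sel$p1prime == "L"))
  expect_true(all(nchar(sel$peptide) >= 7 & nchar(sel$peptide) <= 30))
  # zero events -> empty, protein without eligible sites warns
  expect_equal(nrow(applyEndogenousCleavage(sq, d, 0, w)), 0L)
  expect_warning(
    applyEndogenousCleavage(strrep("A", 40), digestProtein(strrep("A", 40)),
                            5, w), "no eligible")
})

test_that("generated semi peptides classify as semi, never full", {
  ch <- simulateCohort(smallConfig(), seed = 6)
  pt <- ch$peptideTable
  ann <- classifyPeptides(pt$peptides, ch$proteins)
  idx <- match(pt$peptides$stripped_sequence, ann$peptide)
  semi_truth <- ch$truth$is_semi
  cls <- ann$spec_class[idx]
  expect_true(all(cls[semi_truth] %in% c("semi_N", "semi_C")))
  expect_false(any(ann$terminal_excluded[idx][semi_truth]))
  # and every peptide is locatable in its protein
  expect_false(anyNA(idx))
})

test_that("endogenous cleavage concentrates on the designated genes", {
  ch <- simulateCohort(smallConfig(), seed = 7)
  pt <- ch$peptideTable
  ann <- classifyPeptides(pt$peptides, ch$proteins)
  fam <- setNames(rep("hot", 2), ch$config$cleavage_hot_genes)
  share <- proteinFamilyShare(ann, ch$proteins, fam)
  expect_equal(share$share[share$family == "hot"], 0.75, tolerance = 0.05)
  expect_equal(sum(share$share), 1, tolerance = 1e-12)
  # the designated collagen genes also show more semi peptides per sample
  # in the PC than in NAT (higher configured proteolysis share)
  counts <- semiCountsPerProtein(ann, pt, ch$config$cleavage_hot_genes[1])
  comp <- ch$metadata$compartment[match(counts$sample_id,
                                        ch$metadata$sample_id)]
  expect_gt(mean(counts$count[comp == "PC"]),
            mean(counts$count[comp == "NAT"]))
})

test_that("missingness is intensity-dependent in the expected direction", {
  set.seed(8)
  lin <- matrix(2^rnorm(5000, 17, 2), 100, 50)
  cfg <- simConfig()
  out <- applyMissingness(lin, cfg)
  expect_lt(mean(log2(lin[is.na(out)])), mean(log2(lin[!is.na(out)])))
  # extreme settings
  all_miss <- applyMissingness(lin, simConfig(mcar_rate = 1))
  expect_true(all(is.na(all_miss)))
  none <- applyMissingness(lin, simConfig(mnar_midpoint = -100,
                                          mnar_steepness = 1e-9,
                                          mcar_rate = 0))
  expect_false(anyNA(none))
})

test_that("a simulated cohort round-trips through the readers", {
  ch <- simulateCohort(smallConfig(), seed = 11)
  dir <- withr::local_tempdir()
  writeCohort(ch, dir)
  db <- readFasta(file.path(dir, "cohort.fasta"))
  expect_equal(db$accession, ch$proteins$accession)
  expect_equal(db$sequence, ch$proteins$sequence)
  expect_equal(db$gene, ch$proteins$gene)
  pt <- readPeptideTable(file.path(dir, "peptides.tsv"), "wide")
  expect_equal(pt$peptides$stripped_sequence,
               ch$peptideTable$peptides$stripped_sequence)
  expect_equal(unname(pt$intensities),
               unname(ch$peptideTable$intensities), tolerance = 1e-6)
  md <- readMetadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ch$metadata$sample_id)
  expect_equal(md$compartment, ch$metadata$compartment)
})

test_that("noiseless simulation with no effects is flat across samples", {
  cfg <- smallConfig(noise_sd = 1e-12, patient_sd = 1e-12,
                     peptide_offset_sd = 0.5, effect_log2 = 0,
                     size_r_target = 1e-6, marker_r = 1e-6,
                     semi_shares = c(NAT = 0.2, PC = 0.2, TUMOR = 0.2),
                     mcar_rate = 0, mnar_midpoint = -100,
                     mnar_steepness = 1e-9)
  ch <- simulateCohort(cfg, seed = 12)
  lin <- ch$peptideTable$intensities
  rel_spread <- apply(lin, 1, function(r) diff(range(r)) / max(r))
  expect_lt(max(rel_spread), 1e-6)
})
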