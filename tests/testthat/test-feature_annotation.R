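# The 34-dim handcrafted feature space: hydropathy, aromaticity, the
# SS8 -> SS3 reduction, one-hot blocks and the pLDDT mask.

test_that("per-residue hydropathy matches the Kyte-Doolittle scale", {
  expect_equal(residue_hydropathy("I"), 4.5)
  expect_equal(residue_hydropathy("R"), -4.5)
  expect_equal(mean(residue_hydropathy(c("I", "R"))), 0)
  # per-residue mean reproduces whole-protein GRAVY exactly
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "IIRRGGWW", "MKV")
  for (s in seqs) {
    aa <- strsplit(s, "")[[1]]
    expect_equal(mean(residue_hydropathy(aa)),
                 sum(kyte_doolittle[aa]) / length(aa), tolerance = 1e-12)
  }
  expect_error(residue_hydropathy("X"), "nonstandard")
})

test_that("aromaticity indicator averages to whole-protein aromaticity", {
  expect_identical(residue_aromaticity("F"), 1L)
  expect_identical(residue_aromaticity("A"), 0L)
  expect_equal(mean(residue_aromaticity(strsplit("FWYA", "")[[1]])), 0.75)
  expect_error(residue_aromaticity("B"), "nonstandard")
})

test_that("SS8 reduces to SS3 by the standard convention", {
  expect_identical(ss8_to_ss3(c("H", "G", "I")), c("H", "H", "H"))
  expect_identical(ss8_to_ss3(c("E", "B")), c("E", "E"))
  expect_identical(ss8_to_ss3(c("T", "S", "-")), c("C", "C", "C"))
  expect_error(ss8_to_ss3("Q"), "unknown SS8")
})

test_that("residue feature matrix satisfies the 34-dim layout invariants", {
  lay <- feature_layout()
  expect_identical(lay$n, 34L)
  expect_identical(length(lay$names), 34L)
  set.seed(41)
  for (rep in 1:5) {
    L <- sample(5:40, 1)
    aa <- sample(names(kyte_doolittle), L, replace = TRUE)
    ss8 <- sample(c("H", "G", "I", "E", "B", "T", "S", "-"), L, replace = TRUE)
    asa <- rgamma(L, 2, 0.05)
    m <- residue_feature_matrix(aa, ss8, asa)
    expect_identical(dim(m), c(L, 34L))
    # one-hot blocks each sum to exactly 1
    expect_true(all(rowSums(m[, 1:3, drop = FALSE]) == 1))
    expect_true(all(rowSums(m[, 4:11, drop = FALSE]) == 1))
    expect_true(all(rowSums(m[, 15:34, drop = FALSE]) == 1))
    # ss3 one-hot agrees with the reduction of the ss8 argmax
    ss8_codes <- c("H", "G", "I", "E", "B", "T", "S", "-")
    ss3_from_ss8 <- ss8_to_ss3(ss8_codes[max.col(m[, 4:11, drop = FALSE])])
    expect_identical(c("H", "E", "C")[max.col(m[, 1:3, drop = FALSE])],
                     ss3_from_ss8)
    expect_equal(m[, "gravy"], residue_hydropathy(aa))
  }
  expect_error(residue_feature_matrix("A", "H", -1), "non-negative")
})

test_that("assemble_features applies the strict pLDDT rule and masks", {
  dssp <- data.frame(aa = c("M", "K", "V", "F"),
                     ss8 = c("H", "H", "-", "E"),
                     asa = c(10, 20, 30, 40))
  ann <- assemble_features("P1", "MKVF", dssp, plddt = c(0.9, 0.65, 0.7, 0.71))
  expect_s3_class(ann, "protein_annotation")
  expect_identical(ncol(ann$features), 34L)
  # below 0.7 excluded (strict); exactly 0.7 kept
  expect_identical(ann$mask, c(TRUE, FALSE, TRUE, TRUE))
  # percentage-scale pLDDT is normalized
  ann2 <- assemble_features("P1", "MKVF", dssp, plddt = c(90, 65, 70, 71))
  expect_identical(ann2$mask, ann$mask)
  expect_equal(ann2$plddt, c(0.90, 0.65, 0.70, 0.71))
})

test_that("nonstandard residues and uncovered positions are masked out", {
  dssp <- data.frame(aa = c("M", "V"), ss8 = c("H", "E"), asa = c(1, 2),
                     seq_index = c(1L, 3L))
  ann <- assemble_features("P2", "MXVU", dssp, plddt = rep(1, 4))
  # residue 2 (no DSSP coverage + X), residue 4 (U, uncovered)
  expect_identical(ann$mask, c(TRUE, FALSE, TRUE, FALSE))
  # masked-out rows carry all-zero features, masked-in rows valid one-hots
  expect_true(all(ann$features[2, ] == 0))
  expect_equal(sum(ann$features[1, 15:34]), 1)
  expect_error(assemble_features("P3", "MK", dssp, plddt = c(1, 1)),
               "length mismatch")
})

test_that("masked fraction is monotone in the pLDDT threshold", {
  set.seed(7)
  L <- 50
  dssp <- data.frame(aa = sample(names(kyte_doolittle), L, replace = TRUE),
                     ss8 = rep("-", L), asa = runif(L, 0, 100))
  plddt <- runif(L)
  fracs <- vapply(c(0.9, 0.7, 0.5, 0.3, 0), function(thr)
    mean(!assemble_features("P", paste(dssp$aa, collapse = ""), dssp,
                            plddt, plddt_min = thr)$mask), numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("annotation TSV round-trips", {
  dssp <- data.frame(aa = c("M", "K"), ss8 = c("H", "E"), asa = c(5, 6))
  ann <- assemble_features("P1", "MK", dssp, plddt = c(1, 0.5))
  path <- tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$ss3, c("H", "E"))
  expect_identical(tab$mask, c(TRUE, FALSE))
  expect_equal(tab$gravy, unname(kyte_doolittle[c("M", "K")]))
})
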