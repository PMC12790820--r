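# Handcrafted per-residue biochemical features: the 34-dimensional target
# space the informed subspace is trained against.

#' Kyte-Doolittle hydropathy scale
#'
#' Named vector of hydropathy values for the 20 standard amino acids
#' (one-letter codes). The per-protein GRAVY score is the mean of these
#' values over the sequence.
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# canonical orders; these fix the 34-dim layout everywhere in the package
.AA_CODES  <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.SS8_CODES <- c("H", "G", "I", "E", "B", "T", "S", "-")
.SS3_CODES <- c("H", "E", "C")
.AROMATIC  <- c("F", "W", "Y")

#' The fixed 34-dimensional informed feature layout
#'
#' Returns the column layout of the informed subspace: SS3 one-hot (3),
#' SS8 one-hot (8), ASA (1), GRAVY (1), aromaticity (1), amino-acid
#' one-hot (20), in that order. Every component of the package (encoder
#' readouts, adversarial heads, probes, attribution labels) shares this
#' layout.
#'
#' @return A list with `names` (length-34 character vector of feature
#'   names), `tasks` (a list of the six prediction tasks with elements
#'   `name`, `kind` in `c("ce","bce","l1")`, and `idx`, the 1-based slice
#'   into the 34 positions), and `n` (34).
#' @export
feature_layout <- function() {
  nm <- c(paste0("ss3_", .SS3_CODES),
          paste0("ss8_", .SS8_CODES),
          "asa", "gravy", "aromatic",
          paste0("aa_", .AA_CODES))
  tasks <- list(
    list(name = "ss3",        kind = "ce",  idx = 1:3,   classes = .SS3_CODES),
    list(name = "ss8",        kind = "ce",  idx = 4:11,  classes = .SS8_CODES),
    list(name = "asa",        kind = "l1",  idx = 12L),
    list(name = "gravy",      kind = "l1",  idx = 13L),
    list(name = "aromatic",   kind = "bce", idx = 14L),
    list(name = "aa",         kind = "ce",  idx = 15:34, classes = .AA_CODES)
  )
  list(names = nm, tasks = tasks, n = 34L)
}

#' Collapse an eight-state secondary structure code to three states
#'
#' Uses the common DSSP reduction: H, G, I (helices) to H; E, B (strands)
#' to E; T, S and "-" (everything else) to C.
#'
#' @param ss8 Character vector of SS8 codes (`H,G,I,E,B,T,S,-`).
#' @return Character vector of the same length over `H, E, C`.
#' @export
ss8_to_ss3 <- function(ss8) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", "-" = "C")
  bad <- setdiff(unique(ss8), names(map))
  if (length(bad) > 0L)
    stop("unknown SS8 code(s): ", paste(bad, collapse = ", "))
  unname(map[ss8])
}

#' Per-residue Kyte-Doolittle hydropathy
#'
#' @param aa Character vector of one-letter amino-acid codes (the 20
#'   standard residues only).
#' @return Numeric vector of hydropathy values in `[-4.5, 4.5]`. The mean
#'   over a sequence equals the protein GRAVY score.
#' @export
residue_hydropathy <- function(aa) {
  bad <- setdiff(unique(aa), names(kyte_doolittle))
  if (length(bad) > 0L)
    stop("nonstandard amino acid code(s): ", paste(bad, collapse = ", "))
  unname(kyte_doolittle[aa])
}

#' Per-residue aromaticity indicator
#'
#' 1 for F, W and Y, 0 for the other standard residues, so that the
#' sequence mean reproduces the whole-protein aromaticity (fraction of
#' aromatic residues).
#'
#' @inheritParams residue_hydropathy
#' @return Integer vector of 0/1 indicators.
#' @export
residue_aromaticity <- function(aa) {
  bad <- setdiff(unique(aa), .AA_CODES)
  if (length(bad) > 0L)
    stop("nonstandard amino acid code(s): ", paste(bad, collapse = ", "))
  as.integer(aa %in% .AROMATIC)
}

# one-hot helper: codes -> length(codes) x length(levels) 0/1 matrix
.one_hot <- function(x, levels) {
  m <- matrix(0, nrow = length(x), ncol = length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(x), match(x, levels))] <- 1
  m
}

#' Build the 34-column feature matrix for a residue track
#'
#' Low-level constructor used by [assemble_features()] and the synthetic
#' generator: given aligned per-residue amino acids, SS8 codes and ASA
#' values, returns the L x 34 matrix in the fixed layout. SS3, GRAVY,
#' aromaticity and the amino-acid one-hot are derived, guaranteeing the
#' consistency invariants.
#'
#' @param aa Character vector of standard one-letter codes.
#' @param ss8 Character vector of SS8 codes, same length.
#' @param asa Numeric vector of solvent accessibilities (A^2), same length.
#' @return An L x 34 numeric matrix with the [feature_layout()] column names.
#' @export
residue_feature_matrix <- function(aa, ss8, asa) {
  L <- length(aa)
  stopifnot(length(ss8) == L, length(asa) == L)
  if (any(asa < 0)) stop("ASA must be non-negative")
  lay <- feature_layout()
  ss3 <- ss8_to_ss3(ss8)
  m <- cbind(
    .one_hot(ss3, .SS3_CODES),
    .one_hot(ss8, .SS8_CODES),
    asa,
    residue_hydropathy(aa),
    residue_aromaticity(aa),
    .one_hot(aa, .AA_CODES)
  )
  colnames(m) <- lay$names
  m
}

#' Assemble a per-protein annotation from sequence, DSSP records and pLDDT
#'
#' Aligns the sequence with parsed DSSP records (by position within the
#' resolved residues; gaps allowed), computes the 34-dim feature matrix,
#' and builds the training mask. A residue is masked out (excluded from
#' feature-loss training) when any of: it has no structural coverage, its
#' amino acid is nonstandard (X, B, Z, U, O, ...), or its pLDDT is
#' strictly below `plddt_min`. pLDDT values above 1 are treated as
#' percentages and divided by 100.
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid string (may contain nonstandard codes; those
#'   residues are masked, not dropped).
#' @param dssp Data frame from [parse_dssp()], or a data frame with
#'   columns `aa`, `ss8`, `asa` (and optionally `seq_index`, the 1-based
#'   position in `sequence`; defaults to file order).
#' @param plddt Numeric per-residue confidence in `[0,1]` or `[0,100]`,
#'   length `nchar(sequence)`.
#' @param plddt_min Exclusion threshold on the `[0,1]` scale (default 0.7);
#'   the comparison is strict, so a residue at exactly `plddt_min` is kept.
#' @return An object of class `protein_annotation`: a list with
#'   `protein_id`, `sequence`, `features` (L x 34 matrix, zero rows for
#'   uncovered/nonstandard residues), `ss8`, `asa`, `plddt` (normalized to
#'   `[0,1]`), and logical `mask` (TRUE = retained for training).
#' @export
assemble_features <- function(protein_id, sequence, dssp, plddt,
                              plddt_min = 0.7) {
  L <- nchar(sequence)
  aa_seq <- strsplit(sequence, "")[[1]]
  if (length(plddt) != L)
    stop("length mismatch: sequence has ", L, " residues but plddt has ",
         length(plddt))
  if (any(plddt > 1)) plddt <- plddt / 100
  if (any(plddt < 0 | plddt > 1))
    stop("pLDDT values outside [0, 1] after normalization")

  idx <- if (!is.null(dssp$seq_index)) dssp$seq_index else seq_len(nrow(dssp))
  if (any(idx < 1L | idx > L))
    stop("length mismatch: DSSP covers index range [", min(idx), ", ",
         max(idx), "] but sequence has length ", L)
  if (anyDuplicated(idx)) stop("duplicate DSSP records for one residue")

  covered  <- seq_len(L) %in% idx
  ss8 <- rep(NA_character_, L); ss8[idx] <- dssp$ss8
  asa <- rep(NA_real_, L);      asa[idx] <- dssp$asa
  standard <- aa_seq %in% .AA_CODES
  mask <- covered & standard & (plddt >= plddt_min)

  features <- matrix(0, nrow = L, ncol = 34L,
                     dimnames = list(NULL, feature_layout()$names))
  ok <- covered & standard
  if (any(ok))
    features[ok, ] <- residue_feature_matrix(aa_seq[ok], ss8[ok], asa[ok])

  structure(
    list(protein_id = protein_id, sequence = sequence, features = features,
         ss8 = ss8, asa = asa, plddt = plddt, mask = mask,
         plddt_min = plddt_min),
    class = "protein_annotation"
  )
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat("Protein annotation:", x$protein_id, "\n")
  cat("  residues:", nchar(x$sequence),
      " masked-in:", sum(x$mask),
      sprintf(" (pLDDT >= %.2f, standard aa, DSSP-covered)\n", x$plddt_min))
  invisible(x)
}

#' Write a per-protein annotation table as TSV
#'
#' Columns: `index` (1-based), `aa`, `ss8`, `ss3`, `asa`, `gravy`,
#' `aromatic`, `plddt`, `mask`.
#'
#' @param ann A `protein_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  aa <- strsplit(ann$sequence, "")[[1]]
  std <- aa %in% .AA_CODES
  df <- data.frame(
    index = seq_along(aa),
    aa = aa,
    ss8 = ifelse(is.na(ann$ss8), "-", ann$ss8),
    ss3 = ss8_to_ss3(ifelse(is.na(ann$ss8), "-", ann$ss8)),
    asa = ifelse(is.na(ann$asa), NA_real_, ann$asa),
    gravy = ifelse(std, suppressWarnings(kyte_doolittle[aa]), NA_real_),
    aromatic = ifelse(std, as.integer(aa %in% .AROMATIC), NA_integer_),
    plddt = ann$plddt,
    mask = ann$mask
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
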