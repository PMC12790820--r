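# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except what the tests themselves write.

# one classic-format DSSP record with the documented fixed columns:
# serial 1-5, resnum 6-10, chain 12, AA 14, SS 17, ACC 35-38
dssp_line <- function(serial, resnum, chain, aa, ss, acc) {
  sprintf("%5d%5d %s %s  %s%17s%4d", serial, resnum, chain, aa, ss, "", acc)
}

write_dssp_fixture <- function(lines, path = tempfile(fileext = ".dssp")) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  3  1  0  0  0 TOTAL NUMBER OF RESIDUES",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N")
  writeLines(c(header, lines), path)
  path
}

# minimal AlphaFold-style PDB with pLDDT in the B-factor column
write_pdb_fixture <- function(plddt, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_along(plddt), function(i)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, i, i * 1.0, 0, 0, 1.00, plddt[i]), character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_mmcif_fixture <- function(plddt, path = tempfile(fileext = ".cif")) {
  hdr <- c("data_synthetic", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_seq_id",
           "_atom_site.B_iso_or_equiv")
  rows <- vapply(seq_along(plddt), function(i)
    sprintf("ATOM %d CA ALA A %d %.2f", i, i, plddt[i]), character(1))
  writeLines(c(hdr, rows, "#"), path)
  path
}

# planted-motif dataset for the CNN: positives carry a fixed kernel-sized
# additive pattern at a random position
make_motif_data <- function(n, L = 40, D = 20, motif, seed = 1) {
  k <- nrow(motif)
  plmx:::.with_seed(seed, {
    X <- lapply(seq_len(n), function(i) matrix(rnorm(L * D), L, D))
    y <- rep(0:1, length.out = n)
    pos <- integer(n)
    for (i in which(y == 1)) {
      p <- sample.int(L - k + 1L, 1L)
      X[[i]][p:(p + k - 1L), ] <- X[[i]][p:(p + k - 1L), ] + motif
      pos[i] <- p
    }
    list(X = X, y = y, pos = pos)
  })
}

# small synthetic dataset reused by several module tests (D = 48, k = 8)
shared_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(synthetic_spec(
        n_proteins = 40, length_range = c(20, 35), D = 48))
    cache
  }
})

# brute-force tree SHAP oracle: subset enumeration over the features a
# tree actually uses, with the cover-weighted conditional expectation
tree_expvalue <- function(tree, x, S) {
  rec <- function(j) {
    f <- tree$feature[j]
    if (is.na(f)) return(tree$value[j])
    if (f %in% S) {
      if (x[f] <= tree$threshold[j]) rec(tree$left[j]) else rec(tree$right[j])
    } else {
      l <- tree$left[j]; r <- tree$right[j]
      (tree$cover[l] * rec(l) + tree$cover[r] * rec(r)) / tree$cover[j]
    }
  }
  rec(1L)
}

tree_shap_bruteforce <- function(tree, x, n_features) {
  used <- unique(tree$feature[!is.na(tree$feature)])
  phi <- numeric(n_features)
  if (length(used) == 0L) return(phi)
  others <- function(j) setdiff(used, j)
  for (j in used) {
    U <- others(j)
    nU <- length(U)
    for (size in 0:nU) {
      combs <- if (size == 0L) list(integer(0)) else
        utils::combn(U, size, simplify = FALSE)
      w <- factorial(size) * factorial(nU - size) / factorial(nU + 1L)
      for (S in combs) {
        phi[j] <- phi[j] +
          w * (tree_expvalue(tree, x, c(S, j)) - tree_expvalue(tree, x, S))
      }
    }
  }
  phi
}
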