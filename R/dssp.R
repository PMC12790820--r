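# Readers for the structure-derived annotation inputs: classic-format DSSP
# output, and per-residue pLDDT from the B-factor column of AlphaFold-style
# PDB / mmCIF files.

#' Parse a classic-format DSSP output file
#'
#' Reads the per-residue records of a DSSP file: eight-state secondary
#' structure (column 17; blank means unassigned and is reported as the
#' coil code `"-"`) and solvent accessibility (ACC, columns 35-38).
#' Chain-break records (`!` in the amino-acid column) are skipped; their
#' count is attached as the attribute `"n_chain_breaks"`. Lowercase
#' amino-acid letters (DSSP's convention for SS-bonded cysteines) are
#' reported as `C`.
#'
#' @param path Path to a DSSP file.
#' @return A data frame with one row per resolved residue, in file order:
#'   `dssp_index`, `pdb_resnum`, `chain`, `aa`, `ss8`, `asa`.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("malformed DSSP header in '", path,
         "': no '  #  RESIDUE' column-header line found")
  body <- lines[seq.int(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]

  n_breaks <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    if (nchar(ln) < 38L)
      stop("malformed DSSP record at line ", hdr[1] + i, ": '", ln, "'")
    aa <- substr(ln, 14, 14)
    if (aa == "!") { n_breaks <- n_breaks + 1L; next }
    # lowercase letters mark disulphide-bonded cysteines
    if (aa %in% letters) aa <- "C"
    ss <- substr(ln, 17, 17)
    if (ss == " ") ss <- "-"
    recs[[i]] <- data.frame(
      dssp_index = as.integer(substr(ln, 1, 5)),
      pdb_resnum = suppressWarnings(as.integer(substr(ln, 6, 10))),
      chain = trimws(substr(ln, 12, 12)),
      aa = aa,
      ss8 = ss,
      asa = as.numeric(substr(ln, 35, 38))
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(dssp_index = integer(), pdb_resnum = integer(),
               chain = character(), aa = character(), ss8 = character(),
               asa = numeric())
  if (any(is.na(out$asa)))
    stop("malformed DSSP record: non-numeric ACC field in '", path, "'")
  attr(out, "n_chain_breaks") <- n_breaks
  out
}

#' Read per-residue pLDDT from an AlphaFold-style structure file
#'
#' AlphaFold models store the per-residue confidence (pLDDT) in the
#' B-factor column. One value per residue is taken from its CA atom
#' (falling back to the residue's first atom when no CA is present).
#' Values are returned as stored (0-100 for AlphaFold files);
#' [assemble_features()] normalizes to `[0,1]`.
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return Numeric vector of per-residue pLDDT values in residue order.
#' @export
read_plddt <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path)) "mmcif" else "pdb"
  if (format == "pdb") .read_plddt_pdb(path) else .read_plddt_mmcif(path)
}

.read_plddt_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(atoms) == 0L) stop("no ATOM records in '", path, "'")
  name  <- trimws(substr(atoms, 13, 16))
  chain <- substr(atoms, 22, 22)
  resno <- trimws(substr(atoms, 23, 27))  # includes insertion code
  bfac  <- as.numeric(substr(atoms, 61, 66))
  key <- paste(chain, resno)
  res_keys <- unique(key)
  vapply(res_keys, function(k) {
    sel <- which(key == k)
    ca <- sel[name[sel] == "CA"]
    bfac[if (length(ca)) ca[1] else sel[1]]
  }, numeric(1), USE.NAMES = FALSE)
}

.read_plddt_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- grep("^_atom_site\\.", lines, value = TRUE)
  if (length(fields) == 0L) stop("no _atom_site loop in '", path, "'")
  fields <- sub("^_atom_site\\.", "", trimws(fields))
  first_field <- grep("^_atom_site\\.", lines)[1]
  body <- lines[seq.int(first_field + length(fields), length(lines))]
  body <- body[!startsWith(body, "_") & !startsWith(body, "#") &
                 !startsWith(body, "loop_") & nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[[:space:]]+")
  keep <- lengths(rows) == length(fields)
  rows <- rows[keep]
  if (length(rows) == 0L) stop("no parsable atom rows in '", path, "'")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- fields
  atom_col <- intersect(c("label_atom_id", "auth_atom_id"), fields)[1]
  seq_col  <- intersect(c("label_seq_id", "auth_seq_id"), fields)[1]
  if (is.na(atom_col) || is.na(seq_col) || !"B_iso_or_equiv" %in% fields)
    stop("required _atom_site fields missing in '", path, "'")
  key <- paste(if ("label_asym_id" %in% fields) tab$label_asym_id else "",
               tab[[seq_col]])
  res_keys <- unique(key)
  vapply(res_keys, function(k) {
    sel <- which(key == k)
    ca <- sel[tab[[atom_col]][sel] == "CA"]
    as.numeric(tab$B_iso_or_equiv[if (length(ca)) ca[1] else sel[1]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences (names from the headers,
#'   truncated at the first whitespace).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
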