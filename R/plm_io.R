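# Embedding plumbing: a registry of PLM backbones behind one contract,
# dataset splits, and the on-disk archive format.

.backbones <- new.env(parent = emptyenv())

#' Register a PLM backbone
#'
#' A backbone is anything that turns sequences into per-residue embedding
#' matrices: an external PLM wrapped in a loader function, or the built-in
#' synthetic generator. The loader returns one token-row matrix per
#' sequence; `drop_first`/`drop_last` rows are removed (BOS/EOS tokens for
#' BERT-style models) so rows align 1:1 with residues.
#'
#' @param name Backbone tag.
#' @param dim Embedding width D this backbone produces.
#' @param loader Function `(sequences, ...)` returning a named list of
#'   token-row matrices, or `NULL` for a declared-but-unavailable external
#'   backbone (shape metadata only).
#' @param drop_first,drop_last Number of special-token rows to strip.
#' @return The registry entry, invisibly.
#' @export
register_backbone <- function(name, dim, loader = NULL,
                              drop_first = 0L, drop_last = 0L) {
  assign(name, list(name = name, dim = as.integer(dim), loader = loader,
                    drop_first = as.integer(drop_first),
                    drop_last = as.integer(drop_last)),
         envir = .backbones)
  invisible(get(name, envir = .backbones))
}

#' Look up a registered backbone
#' @param name Backbone tag.
#' @return The registry entry (name, dim, loader, token offsets).
#' @export
get_backbone <- function(name) {
  if (!exists(name, envir = .backbones))
    stop("unknown backbone '", name, "'; registered: ",
         paste(ls(.backbones), collapse = ", "))
  get(name, envir = .backbones)
}

# built-in registrations: the three published backbones (external loaders
# not bundled; dims are contracts) and a self-contained synthetic backbone
.register_builtin_backbones <- function() {
  register_backbone("esm2-35m",  dim = 480,  drop_first = 1L, drop_last = 1L)
  register_backbone("esm2-650m", dim = 1280, drop_first = 1L, drop_last = 1L)
  register_backbone("protbert",  dim = 1024, drop_first = 1L, drop_last = 1L)
  register_backbone("synthetic", dim = 64, loader = .synthetic_backbone_loader)
}

# deterministic sequence-only embeddings: a fixed random linear map applied
# to per-residue sequence features (aa one-hot, hydropathy, aromaticity)
# plus seeded noise -- a stand-in PLM for pipelines and tests
.synthetic_backbone_loader <- function(sequences, dim = 64, seed = 42,
                                       noise_sigma = 0.05) {
  A <- .with_seed(seed, matrix(stats::rnorm(dim * 22L, sd = 1 / sqrt(22)),
                               dim, 22L))
  out <- lapply(seq_along(sequences), function(i) {
    aa <- strsplit(sequences[[i]], "")[[1]]
    if (!all(aa %in% .AA_CODES))
      stop("synthetic backbone requires standard residues (protein ",
           names(sequences)[i], ")")
    f <- cbind(.one_hot(aa, .AA_CODES),
               residue_hydropathy(aa) / 4.5,
               residue_aromaticity(aa))
    eps <- .with_seed(seed + i, matrix(stats::rnorm(length(aa) * dim,
                                                    sd = noise_sigma),
                                       length(aa), dim))
    f %*% t(A) + eps
  })
  names(out) <- names(sequences)
  out
}

#' Obtain per-residue embeddings for a set of sequences
#'
#' Runs the registered backbone's loader and strips special-token rows so
#' that every matrix has exactly one row per residue.
#'
#' @param sequences Named character vector of amino-acid sequences (e.g.
#'   from [read_fasta()]).
#' @param backbone Backbone tag (see [register_backbone()]).
#' @param ... Passed to the backbone loader.
#' @return Named list of L x D matrices with attribute `backbone_tag`.
#' @export
get_embeddings <- function(sequences, backbone = "synthetic", ...) {
  bb <- get_backbone(backbone)
  if (is.null(bb$loader))
    stop("backbone '", backbone, "' has no loader attached; register it ",
         "with a loader wrapping the external PLM")
  if (any(nchar(sequences) == 0L))
    stop("empty sequence: ",
         paste(names(sequences)[nchar(sequences) == 0L], collapse = ", "))
  raw <- bb$loader(sequences, ...)
  out <- lapply(seq_along(raw), function(i) {
    m <- raw[[i]]
    keep <- seq.int(1L + bb$drop_first, nrow(m) - bb$drop_last)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) != nchar(sequences[[i]]))
      stop("token rows (", nrow(m), ") do not match sequence length (",
           nchar(sequences[[i]]), ") for protein ", names(sequences)[i])
    m
  })
  names(out) <- names(sequences)
  attr(out, "backbone_tag") <- bb$name
  out
}

#' Split protein ids into train / adversarial-eval / validation / test sets
#'
#' Holds out `frac_heldout` of the proteins as a combined validation+test
#' set (divided evenly, validation first) and a further
#' `frac_adversarial` as the set used to train the residual-subspace
#' probes; everything else is adapter training data.
#'
#' @param ids Character vector of protein ids (>= 20).
#' @param frac_heldout Fraction held out for validation+test (default 0.05).
#' @param frac_adversarial Fraction set aside for probe training
#'   (default 0.05).
#' @param seed RNG seed; the split is deterministic given `ids` and `seed`.
#' @return A `dataset_split`: list of disjoint id vectors `train`,
#'   `adversarial_eval`, `validation`, `test`.
#' @export
make_splits <- function(ids, frac_heldout = 0.05, frac_adversarial = 0.05,
                        seed = 1) {
  n <- length(ids)
  if (n < 20L) stop("need at least 20 ids to form non-empty splits")
  n_held <- max(2L, round(n * frac_heldout))
  n_adv  <- max(1L, round(n * frac_adversarial))
  if (n_held + n_adv >= n) stop("held-out fractions leave no training data")
  .with_seed(seed, {
    ord <- sample(ids)
    held <- ord[seq_len(n_held)]
    adv  <- ord[n_held + seq_len(n_adv)]
    trn  <- ord[-seq_len(n_held + n_adv)]
    n_val <- floor(n_held / 2)
    structure(list(train = trn, adversarial_eval = adv,
                   validation = held[seq_len(n_val)],
                   test = held[-seq_len(n_val)]),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Dataset split: train", length(x$train),
      "| adversarial-eval", length(x$adversarial_eval),
      "| validation", length(x$validation),
      "| test", length(x$test), "\n")
  invisible(x)
}

#' Write / read the embedding archive
#'
#' Embeddings are stored in one binary archive (an RDS file keyed by
#' protein id) with a plain-text manifest TSV (`protein_id`, `length`,
#' `dim`) next to it for inspection. The round trip is bit-exact.
#'
#' @param embeddings Named list of L x D matrices (see [get_embeddings()]).
#' @param path Archive path (`.rds`).
#' @param manifest Manifest path; default `<path>.manifest.tsv`.
#' @return `path`, invisibly.
#' @export
write_embedding_archive <- function(embeddings, path,
                                    manifest = paste0(path, ".manifest.tsv")) {
  saveRDS(list(embeddings = embeddings,
               backbone_tag = attr(embeddings, "backbone_tag"),
               format_version = 1L),
          path)
  man <- data.frame(protein_id = names(embeddings),
                    length = vapply(embeddings, nrow, integer(1)),
                    dim = vapply(embeddings, ncol, integer(1)))
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_archive
#' @export
read_embedding_archive <- function(path) {
  obj <- readRDS(path)
  emb <- obj$embeddings
  attr(emb, "backbone_tag") <- obj$backbone_tag
  emb
}
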