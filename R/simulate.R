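# Synthetic world with known generative ground truth: per-residue
# embeddings built from sampled feature states through a fixed random
# linear map, plus an independent residual latent carrying a protein-level
# label signal. Because the map is linear and full column rank, closed-form
# oracles (ridge / linear probes) exist for everything the adapter is
# supposed to recover, and disentanglement is testable by construction.

#' Specification of a synthetic embedding dataset
#'
#' Describes the generative model used by [simulate_dataset()]:
#' per residue, an amino acid is sampled (giving hydropathy, aromaticity
#' and the one-hot), an SS8 state is sampled from a three-state-biased
#' Markov chain (giving SS3 by reduction), ASA is drawn from a
#' state-dependent gamma, and an independent k-dimensional residual latent
#' `u` is drawn. The embedding is `x = A f + B u + eps` where `f` is the
#' 34-dim feature vector on an internal unit-range scale, `A` (D x 34) and
#' `B` (D x k) are fixed full-column-rank Gaussian maps drawn from the
#' seeds, and `eps ~ N(0, noise_sigma^2)`. The protein label is
#' `label_rule(feature_means, u)`; the default depends only on the
#' residual latent (1 iff the protein mean of `u[,1]` is positive), so
#' handcrafted features alone predict it at chance.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max residues per protein (uniform).
#' @param D Embedding dimension (must exceed `34 + k`).
#' @param k Residual latent dimension (default 8).
#' @param noise_sigma Embedding noise s.d. (default 0.05).
#' @param corrupt_frac Fraction of residues given pLDDT below 0.7 and
#'   garbage feature annotations, to exercise the masking path
#'   (default 0.05).
#' @param feature_embed_seed Seed for the feature states and the map `A`.
#' @param residual_seed Seed for the latent `u` and the map `B`.
#' @param noise_seed Seed for `eps` and the corrupted-residue choice.
#' @param label_rule Function `(feature_means, u)` -> 0/1 label, where
#'   `feature_means` is the protein's 34-vector of mean raw features and
#'   `u` its L x k latent matrix.
#' @param u_protein_weight Share `w` in `[0, 1)` of a protein-level
#'   component in the residual latent: `u_i = sqrt(1 - w^2) e_i + w z`,
#'   with `e_i` per-residue and `z` per-protein standard normals
#'   (default 0, fully residue-local). Downstream-task datasets use a
#'   positive weight so the protein-level label has a protein-level
#'   latent to depend on, mimicking the global sequence context a PLM
#'   spreads over all residues.
#' @param ss3_stay Self-transition probability of the SS3-level Markov
#'   chain (default 0.85, giving realistic secondary-structure runs).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 200, length_range = c(30, 60),
                           D = 64, k = 8, noise_sigma = 0.05,
                           corrupt_frac = 0.05,
                           feature_embed_seed = 101, residual_seed = 202,
                           noise_seed = 303, label_rule = NULL,
                           u_protein_weight = 0, ss3_stay = 0.85) {
  if (D <= 34 + k)
    stop("D must exceed 34 + k = ", 34 + k, " for full-column-rank maps")
  if (is.null(label_rule))
    label_rule <- function(feature_means, u) as.integer(mean(u[, 1]) > 0)
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 D = as.integer(D), k = as.integer(k),
                 noise_sigma = noise_sigma, corrupt_frac = corrupt_frac,
                 feature_embed_seed = feature_embed_seed,
                 residual_seed = residual_seed, noise_seed = noise_seed,
                 label_rule = label_rule,
                 u_protein_weight = u_protein_weight, ss3_stay = ss3_stay),
            class = "synthetic_spec")
}

# internal unit-range scaling of the 34 raw feature channels used inside
# the linear map (raw annotations keep their physical units)
.feature_scale <- function() {
  s <- rep(1, 34)
  lay <- feature_layout()
  s[lay$tasks[[3]]$idx] <- 1 / 50   # ASA, A^2 -> ~unit
  s[lay$tasks[[4]]$idx] <- 1 / 4.5  # GRAVY -> [-1, 1]
  s
}

# SS8 sampling: SS3-level Markov chain with self-transition bias, then a
# within-state emission to the eight fine states
.sample_ss8 <- function(L, stay) {
  trans <- matrix((1 - stay) / 2, 3, 3); diag(trans) <- stay
  emis <- list(H = c(H = 0.70, G = 0.20, I = 0.10),
               E = c(E = 0.85, B = 0.15),
               C = c(T = 0.30, S = 0.30, "-" = 0.40))
  ss3 <- integer(L)
  ss3[1] <- sample.int(3L, 1L)
  for (i in seq_len(L - 1L))
    ss3[i + 1L] <- sample.int(3L, 1L, prob = trans[ss3[i], ])
  vapply(ss3, function(s) {
    e <- emis[[s]]
    sample(names(e), 1L, prob = e)
  }, character(1))
}

#' Simulate a synthetic embedding dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A `plmx_synthetic` list: `embeddings` (named list of L x D
#'   matrices), `annotations` (list of `protein_annotation`), `sequences`,
#'   `labels` (named 0/1 vector), and `truth` (the maps `A`, `B`, the
#'   per-protein latents `u`, the internal feature scaling, and the spec).
#'   Identical specs (same seeds) give bit-identical datasets.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_proteins
  D <- spec$D; k <- spec$k

  # feature states and map A
  feat <- .with_seed(spec$feature_embed_seed, {
    A <- matrix(stats::rnorm(D * 34L, sd = 1 / sqrt(34 + k)), D, 34L)
    lens <- sample(spec$length_range[1]:spec$length_range[2], n,
                   replace = TRUE)
    per <- lapply(lens, function(L) {
      aa <- sample(.AA_CODES, L, replace = TRUE)
      ss8 <- .sample_ss8(L, spec$ss3_stay)
      ss3 <- ss8_to_ss3(ss8)
      asa_mean <- c(H = 35, E = 20, C = 70)[ss3]
      asa <- stats::rgamma(L, shape = 2, scale = asa_mean / 2)
      list(aa = aa, ss8 = ss8, asa = asa)
    })
    list(A = A, per = per, lens = lens)
  })

  # residual latent and map B
  res <- .with_seed(spec$residual_seed, {
    B <- matrix(stats::rnorm(D * k, sd = 1 / sqrt(34 + k)), D, k)
    w <- spec$u_protein_weight
    u <- lapply(feat$lens, function(L) {
      e <- matrix(stats::rnorm(L * k), L, k)
      if (w > 0) {
        z <- stats::rnorm(k)
        sqrt(1 - w^2) * e + w * matrix(z, L, k, byrow = TRUE)
      } else e
    })
    list(B = B, u = u)
  })

  # noise and corruption
  nz <- .with_seed(spec$noise_seed, {
    eps <- lapply(feat$lens, function(L)
      matrix(stats::rnorm(L * D, sd = spec$noise_sigma), L, D))
    corrupt <- lapply(feat$lens, function(L) {
      sel <- stats::runif(L) < spec$corrupt_frac
      list(sel = sel,
           plddt = stats::runif(L, 0.30, 0.69),
           aa = sample(.AA_CODES, L, replace = TRUE),
           ss8 = sample(.SS8_CODES, L, replace = TRUE),
           asa = stats::rgamma(L, shape = 2, scale = 30))
    })
    list(eps = eps, corrupt = corrupt)
  })

  scl <- .feature_scale()
  ids <- sprintf("SYN%04d", seq_len(n))
  embeddings <- vector("list", n); annotations <- vector("list", n)
  sequences <- character(n); labels <- integer(n)

  for (i in seq_len(n)) {
    p <- feat$per[[i]]
    f_raw <- residue_feature_matrix(p$aa, p$ss8, p$asa)
    f_scaled <- sweep(f_raw, 2L, scl, "*")
    x <- f_scaled %*% t(feat$A) + res$u[[i]] %*% t(res$B) + nz$eps[[i]]

    # corrupted residues: low pLDDT, annotations unrelated to the embedding
    cr <- nz$corrupt[[i]]
    aa_ann <- p$aa; ss8_ann <- p$ss8; asa_ann <- p$asa
    if (any(cr$sel)) {
      aa_ann[cr$sel] <- cr$aa[cr$sel]
      ss8_ann[cr$sel] <- cr$ss8[cr$sel]
      asa_ann[cr$sel] <- cr$asa[cr$sel]
    }
    plddt <- ifelse(cr$sel, cr$plddt, 1)
    f_ann <- residue_feature_matrix(aa_ann, ss8_ann, asa_ann)

    ann <- structure(
      list(protein_id = ids[i], sequence = paste(aa_ann, collapse = ""),
           features = f_ann, ss8 = ss8_ann, asa = asa_ann, plddt = plddt,
           mask = plddt >= 0.7, plddt_min = 0.7),
      class = "protein_annotation")

    embeddings[[i]] <- x
    annotations[[i]] <- ann
    sequences[i] <- ann$sequence
    labels[i] <- spec$label_rule(colMeans(f_raw), res$u[[i]])
  }
  names(embeddings) <- ids; names(annotations) <- ids
  names(sequences) <- ids; names(labels) <- ids
  attr(embeddings, "backbone_tag") <- sprintf("synthetic-D%d", D)

  structure(list(embeddings = embeddings, annotations = annotations,
                 sequences = sequences, labels = labels,
                 truth = list(A = feat$A, B = res$B, u = res$u,
                              feature_scale = scl, spec = spec)),
            class = "plmx_synthetic")
}

#' @export
print.plmx_synthetic <- function(x, ...) {
  lens <- vapply(x$embeddings, nrow, integer(1))
  cat("Synthetic embedding dataset:", length(lens), "proteins,",
      sum(lens), "residues, D =", ncol(x$embeddings[[1]]), "\n")
  cat("  labels: ", sum(x$labels), " positive / ", length(x$labels), "\n",
      sep = "")
  invisible(x)
}
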