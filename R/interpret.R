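# Local interpretation of the CNN: pick the most activated filter and
# attribute its activation, position by position, to the input feature
# channels with an exactly-efficient permutation SHAP estimator.

#' Local SHAP attribution for the most activated CNN filter
#'
#' Selects the filter with the maximal single post-ReLU activation along
#' the sequence (ties to the lowest filter index) and, at every valid
#' window position, attributes that filter's activation to the input
#' feature channels. The attribution game at position `p` sets a channel
#' "off" by replacing its contribution with the one computed from the
#' background reference; with the channels "on" the value is the observed
#' activation, so per-position SHAP values sum exactly to
#' `activation(p) - baseline(p)`. Positions whose activation is below 10%
#' of the maximum are flagged low-confidence: attributions in weakly
#' activated regions should be read with caution.
#'
#' @param cnn A fitted `plmx_cnn`.
#' @param X The protein's per-residue matrix (L x D, L >= kernel; shorter
#'   inputs are zero-padded).
#' @param background List of per-residue matrices (or one matrix) used as
#'   the reference distribution; channel references are their column
#'   means. At most `n_background` rows are used.
#' @param n_background Cap on background residues (default 100).
#' @param n_perm Permutations per position for the Shapley estimate
#'   (default 64).
#' @param seed RNG seed for the permutations.
#' @param top Number of top features reported per position (default 5).
#' @return A `local_filter_report`: list with `filter` (selected filter
#'   index), `activation` (per-position post-ReLU activation of that
#'   filter), `baseline` (per-position value with every channel at
#'   reference), `shap` (positions x D matrix), `top_features` (list of
#'   up to `top` feature names per position, by decreasing `|SHAP|`),
#'   `low_confidence` (logical per position), and `all_zero` (TRUE when
#'   no filter activates anywhere; the filter is then chosen by
#'   tie-break).
#' @export
local_filter_attribution <- function(cnn, X, background, n_background = 100,
                                     n_perm = 64, seed = 1, top = 5) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (D != cnn$dim)
    stop("input width ", D, " does not match model width ", cnn$dim)
  acts <- conv_activations(cnn, X)
  fmax <- apply(acts, 2L, max)
  all_zero <- all(fmax == 0)
  filt <- which.max(fmax)   # lowest index on ties / all-zero
  a <- acts[, filt]
  k <- cnn$kernel
  W <- matrix(cnn$params$W[, filt], nrow = k, byrow = TRUE)  # k x D
  bias <- cnn$params$b[filt]

  if (is.matrix(background)) background <- list(background)
  bgm <- do.call(rbind, background)
  if (nrow(bgm) > n_background) bgm <- bgm[seq_len(n_background), , drop = FALSE]
  bg <- colMeans(bgm)

  Xp <- if (nrow(X) < k) rbind(X, matrix(0, k - nrow(X), D)) else X
  npos <- nrow(Xp) - k + 1L
  ref <- colSums(W) * bg                     # per-channel reference contribution
  feat_names <- if (!is.null(colnames(X))) colnames(X) else
    paste0("feature_", seq_len(D))

  .with_seed(seed, {
    shap <- matrix(0, npos, D, dimnames = list(NULL, feat_names))
    baseline <- numeric(npos)
    for (p in seq_len(npos)) {
      con <- colSums(W * Xp[p:(p + k - 1L), , drop = FALSE])
      shap[p, ] <- .permutation_shap_relu(con, ref, bias, n_perm)
      baseline[p] <- max(sum(ref) + bias, 0)
    }
    top_features <- lapply(seq_len(npos), function(p) {
      ord <- order(-abs(shap[p, ]), seq_len(D))
      feat_names[ord[seq_len(min(top, D))]]
    })
    structure(list(filter = filt, activation = a, baseline = baseline,
                   shap = shap, top_features = top_features,
                   low_confidence = a < 0.1 * max(a),
                   all_zero = all_zero, kernel = k),
              class = "local_filter_report")
  })
}

#' @export
print.local_filter_report <- function(x, ...) {
  cat("Local filter attribution: filter", x$filter,
      if (x$all_zero) "(warning: all activations zero, tie-break choice)",
      "\n")
  cat("  positions:", length(x$activation),
      " max activation:", signif(max(x$activation), 4), "\n")
  p <- which.max(x$activation)
  cat("  top features at the most activated position (", p, "): ",
      paste(x$top_features[[p]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write attribution reports to disk
#'
#' Writes an [global_attribution()] report as TSV plus a JSON summary, or
#' a [local_filter_attribution()] report as JSON.
#'
#' @param report An `attribution_report` or `local_filter_report`.
#' @param path Output path without extension; `.tsv`/`.json` are
#'   appended as applicable.
#' @return The paths written, invisibly.
#' @export
write_attribution <- function(report, path) {
  if (inherits(report, "attribution_report")) {
    tsv <- paste0(path, ".tsv")
    jsn <- paste0(path, ".json")
    utils::write.table(as.data.frame(report), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(base_value = attr(report, "base_value"),
                              features = as.data.frame(report)),
                         jsn, auto_unbox = TRUE, digits = NA)
    return(invisible(c(tsv, jsn)))
  }
  if (inherits(report, "local_filter_report")) {
    jsn <- paste0(path, ".json")
    jsonlite::write_json(
      list(filter = report$filter, activation = report$activation,
           baseline = report$baseline,
           shap = apply(report$shap, 1L, as.list),
           top_features = report$top_features,
           low_confidence = report$low_confidence,
           all_zero = report$all_zero),
      jsn, auto_unbox = TRUE, digits = NA)
    return(invisible(jsn))
  }
  stop("unsupported report class: ", paste(class(report), collapse = "/"))
}
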