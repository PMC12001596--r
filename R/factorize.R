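#' Center and scale matrix columns
#'
#' Columns are centered to mean zero and, if `scale = TRUE`, divided by
#' their sample standard deviation. Zero-variance columns cannot be scaled;
#' they are removed from the returned matrix and reported in the
#' `"zero_variance"` attribute so that the caller can account for them.
#'
#' @param Z numeric matrix with at least 2 rows.
#' @param center,scale logical.
#' @return The standardized matrix (zero-variance columns removed when
#'   scaling), with attribute `zero_variance` naming removed columns.
#' @export
standardize_columns <- function(Z, center = TRUE, scale = TRUE) {
  if (!is.matrix(Z) || nrow(Z) < 2L)
    stop("Z must be a matrix with at least 2 rows")
  sds <- apply(Z, 2L, stats::sd)
  zv <- colnames(Z)[sds == 0]
  if (is.null(zv)) zv <- which(sds == 0)  # unnamed matrix: report indices
  if (scale && length(zv)) Z <- Z[, sds > 0, drop = FALSE]
  out <- scale(Z, center = center, scale = scale)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "zero_variance") <- zv
  out
}

#' Principal-component scores of a standardized matrix
#'
#' Thin SVD-based PCA. Scores are the projections on the leading principal
#' axes and satisfy `var(scores[, j]) == eigenvalues[j]`. A deterministic
#' sign convention is applied: each loading column is flipped so that its
#' largest-magnitude entry is positive, making outputs reproducible across
#' platforms (PCA signs are otherwise arbitrary).
#'
#' @param Z centered (and typically scaled) numeric matrix.
#' @param n_comp number of components requested; truncated to the numerical
#'   rank of `Z` with a warning when it exceeds it.
#' @return list with `scores` (nrow(Z) x k), `eigenvalues` (all
#'   min(nrow-1, ncol) eigenvalues, descending) and `loadings`
#'   (ncol(Z) x k, unit-norm columns), where `k = min(n_comp, rank)`.
#' @export
pca_scores <- function(Z, n_comp) {
  if (n_comp < 1L) stop("n_comp must be >= 1")
  if (n_comp > min(nrow(Z) - 1L, ncol(Z)))
    stop("n_comp exceeds min(nrow - 1, ncol)")
  sv <- svd(Z)
  nev <- min(nrow(Z) - 1L, ncol(Z))
  eig <- (sv$d^2 / (nrow(Z) - 1L))[seq_len(nev)]
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  k <- n_comp
  if (n_comp > rank) {
    warning("n_comp (", n_comp, ") exceeds numerical rank (", rank,
            "); returning ", rank, " component(s)")
    k <- rank
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    V[which.max(abs(V[, j])), j] < 0
  }, NA)
  V[, flip] <- -V[, flip]
  U[, flip] <- -U[, flip]
  scores <- U %*% diag(d, nrow = k)
  rownames(scores) <- rownames(Z)
  rownames(V) <- colnames(Z)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = eig, loadings = V)
}

#' @rdname pathway_scores
#' @export
pathway_scores_pca <- function(qt, pathway, n_comp) {
  prep <- .pathway_submatrix(qt, pathway)
  Z <- standardize_columns(prep$Z)
  m_star <- min(n_comp, ncol(Z))
  p <- pca_scores(Z, m_star)
  structure(list(pathway_id = prep$pathway_id,
                 scores = p$scores,
                 eigenvalues = p$eigenvalues,
                 loadings = p$loadings,
                 method = "pca",
                 block_weights = NULL),
            class = "score_block")
}

#' Per-pathway score matrices
#'
#' `pathway_scores_pca` runs a single PCA on the standardized quantified
#' sub-matrix of a pathway and keeps `m* = min(n_comp, #usable metabolites)`
#' component scores; `n_comp` is normally the number of fixed effects to be
#' tested, so enough information is retained to estimate each effect.
#'
#' `pathway_scores_mfa` is the partial-PCA variant in the spirit of
#' Multiple Factor Analysis: the sub-matrix is split into blocks by
#' `block_var` (by default the time factor), each block is standardized and
#' analysed by its own PCA, block scores are rescaled by the block weight
#' `1/sqrt(lambda1)` (first eigenvalue of the block; `weight =
#' "inv_lambda1"` uses `1/lambda1` instead) so that no block dominates, and
#' the weighted block scores are stacked back in the original row order.
#' Because each block is centered independently, any between-block (e.g.
#' time) mean signal is removed by construction, which is why this variant
#' is not recommended for testing the blocking effect itself. Block
#' component signs are aligned to the global-PCA loadings of the same
#' pathway (flipped when the dot product is negative); without this the
#' stacked scores would mix arbitrary per-block signs.
#'
#' Pathways with fewer than two usable (quantified, non-constant)
#' metabolites cannot be analysed: a classed error
#' (`pathlmm_pathway_skip`) is signalled, which [pathway_test] converts
#' into a skip-report entry.
#'
#' @param qt a [quant_table].
#' @param pathway character vector of metabolite ids (or a single pathway
#'   id's member set).
#' @param n_comp number of score columns to retain (usually the number of
#'   fixed effects, F).
#' @param block_var design factor defining the blocks (default `"time"`).
#' @param weight block weighting rule, `"inv_sqrt_lambda1"` (standard MFA
#'   balancing, default) or `"inv_lambda1"`.
#' @return A `score_block`: list with `pathway_id`, `scores` (row-aligned
#'   to `qt`), `eigenvalues`, `loadings`, `method`, and for MFA
#'   `block_weights` (one per block level).
#' @name pathway_scores
#' @export
pathway_scores_mfa <- function(qt, pathway, n_comp, block_var = "time",
                               weight = c("inv_sqrt_lambda1", "inv_lambda1")) {
  weight <- match.arg(weight)
  prep <- .pathway_submatrix(qt, pathway)
  blocks <- qt$design[[block_var]]
  if (nlevels(blocks) < 1L) stop("block_var has no levels")
  small <- table(blocks) < 3L
  if (any(small))
    stop("block too small (fewer than 3 observations): ",
         paste(names(small)[small], collapse = ", "))

  # drop columns that are constant in any block, so every partial PCA sees
  # the same metabolites
  zv <- Reduce(union, lapply(levels(blocks), function(b) {
    Zb <- prep$Z[blocks == b, , drop = FALSE]
    s <- apply(Zb, 2L, stats::sd)
    colnames(Zb)[s == 0]
  }))
  Z <- prep$Z[, setdiff(colnames(prep$Z), zv), drop = FALSE]
  if (ncol(Z) < 2L)
    .skip_pathway(prep$pathway_id,
                  "fewer than 2 metabolites usable in all blocks")
  m_star <- min(n_comp, ncol(Z))

  glob <- pca_scores(standardize_columns(Z), m_star)
  m_star <- ncol(glob$scores)

  scores <- matrix(NA_real_, nrow(Z), m_star,
                   dimnames = list(rownames(prep$Z),
                                   paste0("PC", seq_len(m_star))))
  bw <- stats::setNames(numeric(nlevels(blocks)), levels(blocks))
  for (b in levels(blocks)) {
    rows <- which(blocks == b)
    Zb <- standardize_columns(Z[rows, , drop = FALSE])
    if (ncol(Zb) < m_star)
      .skip_pathway(prep$pathway_id,
                    paste0("block ", b, " has rank below ", m_star))
    pb <- pca_scores(Zb, m_star)
    if (ncol(pb$scores) < m_star)
      .skip_pathway(prep$pathway_id,
                    paste0("block ", b, " has rank below ", m_star))
    l1 <- pb$eigenvalues[1L]
    if (l1 <= 0) stop("zero first eigenvalue in block ", b)
    bw[b] <- if (weight == "inv_sqrt_lambda1") 1 / sqrt(l1) else 1 / l1
    # align block components with the global loadings (restricted to the
    # columns surviving in the block)
    gl <- glob$loadings[colnames(Zb), , drop = FALSE]
    for (j in seq_len(m_star)) {
      if (sum(pb$loadings[, j] * gl[, j]) < 0) {
        pb$loadings[, j] <- -pb$loadings[, j]
        pb$scores[, j] <- -pb$scores[, j]
      }
    }
    scores[rows, ] <- pb$scores * bw[b]
  }
  structure(list(pathway_id = prep$pathway_id,
                 scores = scores,
                 eigenvalues = glob$eigenvalues,
                 loadings = glob$loadings,
                 method = "mfa",
                 block_weights = bw),
            class = "score_block")
}

#' @exportS3Method base::print
print.score_block <- function(x, ...) {
  cat("score_block [", x$method, "] pathway ", x$pathway_id, ": ",
      nrow(x$scores), " x ", ncol(x$scores), " scores\n", sep = "")
  invisible(x)
}

# extract the quantified, non-constant sub-matrix of a pathway, or signal a
# classed skip condition when fewer than 2 columns survive
.pathway_submatrix <- function(qt, pathway) {
  stopifnot(inherits(qt, "quant_table"))
  id <- attr(pathway, "pathway_id")
  if (is.null(id)) id <- NA_character_
  members <- intersect(as.character(pathway), colnames(qt$values))
  if (length(members) < 2L)
    .skip_pathway(id, "fewer than 2 quantified metabolites")
  Z <- qt$values[, members, drop = FALSE]
  sds <- apply(Z, 2L, stats::sd)
  Z <- Z[, sds > 0, drop = FALSE]
  if (ncol(Z) < 2L)
    .skip_pathway(id, "fewer than 2 non-constant metabolites")
  list(pathway_id = id, Z = Z)
}

.skip_pathway <- function(pathway_id, reason) {
  stop(structure(class = c("pathlmm_pathway_skip", "error", "condition"),
                 list(message = reason, call = sys.call(-1L),
                      pathway_id = pathway_id)))
}
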