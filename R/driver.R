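#' Simes' p-value combination
#'
#' Aggregates the component p-values of one pathway into a single p-value
#' for the intersection null hypothesis: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the Simes p-value is
#' \eqn{\min_j m\, p_{(j)} / j}, clipped to \[0, 1\]. The procedure is
#' exact under independence and PRDS and is known to be robust to moderate
#' deviations from those assumptions.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; NAs are removed
#'   with a warning (the effective `m` shrinks accordingly).
#' @return A single p-value, or `NA` if no non-missing value remains.
#' @export
simes <- function(pvals) {
  if (anyNA(pvals)) {
    warning("NA component p-value(s) removed before Simes aggregation")
    pvals <- pvals[!is.na(pvals)]
  }
  m <- length(pvals)
  if (m == 0L) return(NA_real_)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  p <- sort(pvals)
  min(1, min(m * p / seq_len(m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values. NAs are passed through unchanged and do
#' not count towards the number of tests.
#'
#' @param pvals numeric vector of p-values (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Pathway-level differential analysis
#'
#' The main entry point. For every pathway with at least
#' `min_pathway_size` quantified metabolites, a score matrix is extracted
#' (global PCA, or the per-time-block partial-PCA variant when
#' `method = "mfa"`; see [pathway_scores_pca] and [pathway_scores_mfa])
#' with `m* = min(F, #usable metabolites)` columns, `F` being the number
#' of tested fixed effects. Each score column is tested for every effect
#' with a mixed-model likelihood-ratio test ([lrt_effect]); the `m*`
#' component p-values of a pathway are combined with [simes]; finally,
#' separately for each effect, the pathway p-values are adjusted across
#' pathways with [bh_adjust].
#'
#' When `method = "mfa"` and an effect coincides with the MFA blocking
#' variable (by default time), the partial analyses erase precisely that
#' between-block signal, so the corresponding rows are flagged
#' `"mfa_block_effect_not_recommended"` in the `note` column.
#'
#' @param qt a [quant_table].
#' @param ps a [pathway_set] (filtered internally against `qt`).
#' @param effects ordered character vector of the model's fixed effects
#'   (subset of `c("time", "condition")`); its length defines `F`, the
#'   number of score columns retained per pathway.
#' @param test_effects effects actually tested and reported (defaults to
#'   all of `effects`); restricting it skips needless restricted-model
#'   fits in large simulation studies.
#' @param method `"pca"` (global PCA) or `"mfa"` (partial PCA per block).
#' @param alpha significance level for the `significant` flag (on the
#'   BH-adjusted p-value, strict inequality).
#' @param min_pathway_size minimum quantified pathway size (>= 2).
#' @param mfa_block_var blocking factor for `method = "mfa"`.
#' @param mfa_weight block weighting rule, see [pathway_scores_mfa].
#' @return A data.frame of class `pathway_test_result` with one row per
#'   pathway x effect: `pathway_id`, `effect`, `n_metabolites` (quantified
#'   members), `n_components` (`m*`), `comp_p_1 ... comp_p_F` (component
#'   p-values, NA-padded), `simes_p`, `adj_p`, `significant`, `note`.
#'   Pathways that could not be analysed are listed in the `"skipped"`
#'   attribute (pathway_id, reason).
#' @examples
#' spec <- generator_spec(seed = 42)
#' base <- generate_dataset(spec)
#' res <- pathway_test(base$qt, base$pathways, method = "pca")
#' head(res)
#' @export
pathway_test <- function(qt, ps,
                         effects = c("time", "condition"),
                         test_effects = effects,
                         method = c("pca", "mfa"),
                         alpha = 0.05,
                         min_pathway_size = 2L,
                         mfa_block_var = "time",
                         mfa_weight = "inv_sqrt_lambda1") {
  method <- match.arg(method)
  stopifnot(inherits(qt, "quant_table"), inherits(ps, "pathway_set"))
  if (!length(effects)) stop("'effects' must be nonempty")
  if (!all(effects %in% c("time", "condition")))
    stop("effects must be a subset of c('time', 'condition')")
  if (!all(test_effects %in% effects))
    stop("test_effects must be a subset of effects")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (method == "mfa" && !mfa_block_var %in% names(qt$design))
    stop("mfa_block_var not found in the design")

  ps <- suppressMessages(filter_pathways(ps, qt, min_size = min_pathway_size))
  F_eff <- length(effects)
  engine <- .lmm_engine(qt$design, effects, test_effects)

  rows <- list()
  skipped <- list()
  for (id in names(ps$pathways)) {
    members <- structure(ps$pathways[[id]], pathway_id = id)
    sb <- tryCatch(
      if (method == "pca") pathway_scores_pca(qt, members, F_eff)
      else pathway_scores_mfa(qt, members, F_eff, block_var = mfa_block_var,
                              weight = mfa_weight),
      pathlmm_pathway_skip = function(e) e,
      error = function(e) e)
    if (inherits(sb, "condition")) {
      skipped[[id]] <- conditionMessage(sb)
      next
    }
    m_star <- ncol(sb$scores)
    # component x effect p-values
    pmat <- matrix(NA_real_, m_star, length(test_effects),
                   dimnames = list(NULL, test_effects))
    for (j in seq_len(m_star)) {
      lrt <- engine(sb$scores[, j])
      pmat[j, lrt$effect] <- lrt$pvalue
    }
    for (f in test_effects) {
      comp <- rep(NA_real_, F_eff)
      comp[seq_len(m_star)] <- pmat[, f]
      sp <- if (all(is.na(pmat[, f]))) NA_real_
            else suppressWarnings(simes(pmat[, f]))
      note <- if (method == "mfa" && identical(f, mfa_block_var))
        "mfa_block_effect_not_recommended" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = id, effect = f,
        n_metabolites = length(members),
        n_components = m_star,
        t(stats::setNames(comp, paste0("comp_p_", seq_len(F_eff)))),
        simes_p = sp, note = note,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no pathway could be analysed")
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  for (f in test_effects) {
    sel <- res$effect == f
    res$adj_p[sel] <- bh_adjust(res$simes_p[sel])
  }
  res$significant <- !is.na(res$adj_p) & res$adj_p < alpha
  res <- res[c("pathway_id", "effect", "n_metabolites", "n_components",
               paste0("comp_p_", seq_len(F_eff)), "simes_p", "adj_p",
               "significant", "note")]
  rownames(res) <- NULL
  attr(res, "skipped") <- data.frame(
    pathway_id = names(skipped),
    reason = unlist(skipped, use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  class(res) <- c("pathway_test_result", "data.frame")
  res
}

#' Write a results table to TSV
#'
#' @param res a `pathway_test_result` (or any data.frame).
#' @param path output file.
#' @return Invisibly, `res`.
#' @export
write_results <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}
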