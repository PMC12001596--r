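#' Per-metabolite mixed-model tests
#'
#' Tests each metabolite individually with the same longitudinal mixed
#' model used at the pathway level ([fit_lmm] / [lrt_effect]) on the raw
#' quantifications. Constant metabolites get an NA p-value. These
#' per-feature calls are the first stage of the over-representation
#' comparator.
#'
#' @param qt a [quant_table].
#' @param effect the fixed effect to test (`"time"` or `"condition"`).
#' @param adjust apply BH correction across metabolites. Leave `FALSE` for
#'   null (type-I error) experiments, where no signal is expected and a
#'   metabolite-level correction would empty the significant set.
#' @return data.frame with `metabolite`, `pvalue` (raw) and `adj_p`
#'   (BH-adjusted, equal to `pvalue` when `adjust = FALSE` is requested
#'   downstream; both columns are always reported).
#' @export
metabolite_tests <- function(qt, effect = c("condition", "time"),
                             adjust = TRUE) {
  effect <- match.arg(effect)
  stopifnot(inherits(qt, "quant_table"))
  engine <- .lmm_engine(qt$design, c("time", "condition"), effect)
  pv <- vapply(colnames(qt$values), function(j) {
    x <- qt$values[, j]
    if (stats::sd(x) == 0) return(NA_real_)
    engine(x)$pvalue
  }, 0)
  data.frame(metabolite = colnames(qt$values),
             pvalue = unname(pv),
             adj_p = bh_adjust(unname(pv)),
             stringsAsFactors = FALSE)
}

#' One-sided over-representation p-value
#'
#' Hypergeometric upper-tail probability of observing at least the
#' realized overlap between the significant set and a pathway, given the
#' background: `P(X >= |significant & pathway|)` for X hypergeometric with
#' `N = |background|`, `K = |significant|`, `n = |pathway|`. This is the
#' one-sided ("greater") Fisher exact test on the 2x2 membership x
#' significance table.
#'
#' @param significant character vector of significant metabolites (subset
#'   of `background`).
#' @param pathway character vector of pathway members (subset of
#'   `background`).
#' @param background character vector, the metabolite universe.
#' @return A p-value.
#' @export
fisher_ora <- function(significant, pathway, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background set is empty")
  significant <- unique(as.character(significant))
  pathway <- unique(as.character(pathway))
  if (!all(pathway %in% background))
    stop("pathway members outside the background set")
  if (!all(significant %in% background))
    stop("significant metabolites outside the background set")
  x <- length(intersect(significant, pathway))
  stats::phyper(x - 1L, m = length(significant),
                n = length(background) - length(significant),
                k = length(pathway), lower.tail = FALSE)
}

#' Over-representation analysis of pathways
#'
#' The enrichment comparator: metabolites are tested individually with the
#' longitudinal mixed model ([metabolite_tests]), declared significant at
#' `metab_alpha` (on BH-adjusted p-values unless `adjust_metabolites =
#' FALSE`), and each pathway is tested for over-representation of
#' significant metabolites with the one-sided Fisher exact test
#' ([fisher_ora]); pathway p-values are BH-corrected across pathways.
#' Metabolites with NA p-values are excluded from both the significant set
#' and the background.
#'
#' @param qt a [quant_table].
#' @param ps a [pathway_set] (filtered internally against `qt`).
#' @param effect fixed effect to test.
#' @param background metabolite universe; defaults to all quantified
#'   metabolites, and may be widened to a larger identifiable-metabolite
#'   reference list.
#' @param metab_alpha metabolite-level significance threshold.
#' @param adjust_metabolites BH-correct metabolite p-values before
#'   thresholding (disable for null experiments).
#' @param alpha pathway-level significance threshold (on adjusted p).
#' @param min_pathway_size minimum quantified pathway size.
#' @return data.frame of class `ora_result`, one row per pathway:
#'   `pathway_id`, `effect`, `n_metabolites`, `n_significant`,
#'   `pct_significant_metabolites`, `pvalue`, `adj_p`, `significant`.
#' @export
ora_test <- function(qt, ps, effect = c("condition", "time"),
                     background = NULL, metab_alpha = 0.05,
                     adjust_metabolites = TRUE, alpha = 0.05,
                     min_pathway_size = 2L) {
  effect <- match.arg(effect)
  stopifnot(inherits(qt, "quant_table"), inherits(ps, "pathway_set"))
  ps <- suppressMessages(filter_pathways(ps, qt, min_size = min_pathway_size))
  mt <- metabolite_tests(qt, effect)
  ok <- !is.na(mt$pvalue)
  use_p <- if (adjust_metabolites) mt$adj_p else mt$pvalue
  sig <- mt$metabolite[ok & use_p < metab_alpha]
  if (is.null(background)) background <- colnames(qt$values)
  background <- setdiff(unique(as.character(background)),
                        mt$metabolite[!ok])
  res <- do.call(rbind, lapply(names(ps$pathways), function(id) {
    members <- intersect(ps$pathways[[id]], background)
    p <- if (length(members)) fisher_ora(sig, members, background)
         else NA_real_
    nsig <- length(intersect(sig, members))
    data.frame(pathway_id = id, effect = effect,
               n_metabolites = length(ps$pathways[[id]]),
               n_significant = nsig,
               pct_significant_metabolites =
                 if (length(members)) 100 * nsig / length(members)
                 else NA_real_,
               pvalue = p, stringsAsFactors = FALSE)
  }))
  res$adj_p <- bh_adjust(res$pvalue)
  res$significant <- !is.na(res$adj_p) & res$adj_p < alpha
  rownames(res) <- NULL
  attr(res, "n_significant_metabolites") <- length(sig)
  attr(res, "background_size") <- length(background)
  class(res) <- c("ora_result", "data.frame")
  res
}
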