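#' Ground-truth categorization of simulated pathways
#'
#' Partitions the tested pathways of a simulation run into three
#' categories: `differential` (explicitly selected for effect injection),
#' `overlapping` (not selected but sharing at least one target metabolite
#' with a selected pathway — no clean ground-truth label exists for
#' these), and `non_differential` (no target metabolite).
#'
#' @param ps the [pathway_set] that was tested.
#' @param selected character vector of injected pathway ids.
#' @param target_metabolites character vector of all injected metabolites.
#' @return An object of class `pathway_truth`: list of the three id sets.
#' @export
categorize <- function(ps, selected, target_metabolites) {
  stopifnot(inherits(ps, "pathway_set"))
  if (!all(selected %in% names(ps$pathways)))
    stop("selected pathways not all present in the pathway set")
  ids <- names(ps$pathways)
  rest <- setdiff(ids, selected)
  shares <- vapply(rest, function(id)
    length(intersect(ps$pathways[[id]], target_metabolites)) > 0L, NA)
  structure(list(differential = selected,
                 overlapping = rest[shares],
                 non_differential = rest[!shares]),
            class = "pathway_truth")
}

#' @exportS3Method base::print
print.pathway_truth <- function(x, ...) {
  cat("pathway_truth: ", length(x$differential), " differential, ",
      length(x$overlapping), " overlapping, ",
      length(x$non_differential), " non-differential\n", sep = "")
  invisible(x)
}

#' Confusion counts and summary rates for one simulation run
#'
#' Crosses the significance calls of a results table with a
#' [categorize]d ground truth. Differential pathways count as true
#' positives / false negatives, non-differential ones as false positives /
#' true negatives; overlapping pathways have no ground truth and are
#' tallied separately as positive/negative. PPV is `tp / (tp + fp)`, or
#' `NA` when nothing is declared positive (no rate can be computed);
#' sensitivity is `tp / (tp + fn)`.
#'
#' @param results data.frame with columns `pathway_id` and the p-value
#'   column `p_col`; typically a [pathway_test] or [ora_test] result
#'   restricted to one effect.
#' @param truth a `pathway_truth`.
#' @param alpha significance threshold applied to `p_col` (strict).
#' @param p_col which p-value column defines a positive call (adjusted
#'   p-values for power studies; `"simes_p"`/`"pvalue"` for raw-p type-I
#'   experiments).
#' @return An object of class `eval_report`: list with `tp`, `tn`, `fp`,
#'   `fn`, `pos_overlap`, `neg_overlap`, `ppv`, `sensitivity`.
#' @export
confusion <- function(results, truth, alpha = 0.05, p_col = "adj_p") {
  stopifnot(inherits(truth, "pathway_truth"))
  if (!p_col %in% names(results)) stop("no column '", p_col, "' in results")
  all_ids <- c(truth$differential, truth$overlapping, truth$non_differential)
  extra <- setdiff(results$pathway_id, all_ids)
  if (length(extra))
    stop("result pathway(s) not categorized: ", paste(extra, collapse = ", "))
  p <- results[[p_col]]
  pos <- results$pathway_id[!is.na(p) & p < alpha]
  neg <- setdiff(results$pathway_id, pos)
  tp <- length(intersect(pos, truth$differential))
  fn <- length(intersect(neg, truth$differential))
  fp <- length(intersect(pos, truth$non_differential))
  tn <- length(intersect(neg, truth$non_differential))
  po <- length(intersect(pos, truth$overlapping))
  no <- length(intersect(neg, truth$overlapping))
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 pos_overlap = po, neg_overlap = no,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat("eval_report: TP", x$tp, "FP", x$fp, "FN", x$fn, "TN", x$tn,
      "| overlap +", x$pos_overlap, "-", x$neg_overlap, "\n")
  cat("  PPV =", format(x$ppv), " sensitivity =", format(x$sensitivity), "\n")
  invisible(x)
}

#' Pool evaluation reports over replicates
#'
#' Sums the confusion counts of several [confusion] reports and recomputes
#' PPV and sensitivity on the totals (rates on pooled counts, not averaged
#' per-replicate rates).
#'
#' @param reports list of `eval_report` objects.
#' @return A pooled `eval_report`.
#' @export
combine_reports <- function(reports) {
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, NA, "eval_report")))
  tot <- function(f) sum(vapply(reports, `[[`, 0, f))
  tp <- tot("tp"); fp <- tot("fp"); fn <- tot("fn")
  structure(list(tp = tp, tn = tot("tn"), fp = fp, fn = fn,
                 pos_overlap = tot("pos_overlap"),
                 neg_overlap = tot("neg_overlap"),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "eval_report")
}

#' Fraction of differential metabolites in overlapping pathways
#'
#' For each overlapping pathway, the fraction of its members that were
#' injected (`|members & targets| / |members|`). The fraction can reach 1
#' when an overlapping pathway is entirely contained in a differential
#' one. Comparing this fraction between pathways a method declares
#' positive and negative shows whether its calls on overlapping pathways
#' track the actual amount of injected signal.
#'
#' @param ps the tested [pathway_set].
#' @param truth a `pathway_truth`.
#' @param target_metabolites character vector of injected metabolites.
#' @return Named numeric vector over `truth$overlapping`.
#' @export
overlap_diff_fraction <- function(ps, truth, target_metabolites) {
  stopifnot(inherits(ps, "pathway_set"), inherits(truth, "pathway_truth"))
  vapply(stats::setNames(truth$overlapping, truth$overlapping),
         function(id) {
           mem <- ps$pathways[[id]]
           length(intersect(mem, target_metabolites)) / length(mem)
         }, 0)
}
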