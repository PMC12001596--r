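#' Longitudinal metabolite quantification table
#'
#' A `quant_table` couples a samples x metabolites matrix of nonnegative
#' quantifications (e.g. NMR relative abundances) with its experimental
#' design: each row of the matrix is one observation of one individual at
#' one time point, and each individual belongs to exactly one condition.
#' Rows are canonicalized to time-major order (all individuals at the first
#' time point, then the second, ...), so block operations on time are
#' contiguous.
#'
#' @param values numeric matrix (observations x metabolites), nonnegative,
#'   no missing values, with unique column names (metabolite identifiers).
#' @param design data.frame with columns `sample_id` (unique character,
#'   matching `rownames(values)`), `individual`, `time` and `condition`.
#' @return An object of class `quant_table`: a list with elements `values`
#'   and `design` (design columns coerced to factors; time levels sorted
#'   numerically when all level labels are numeric, lexicographically
#'   otherwise).
#'
#' @details Invariants enforced: no missing quantifications; at most one
#'   observation per (individual, time) pair; a single condition per
#'   individual. Incomplete designs (missing individual x time cells) are
#'   allowed, matching unbalanced longitudinal studies.
#' @export
quant_table <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique metabolite column names")
  req <- c("sample_id", "individual", "time", "condition")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (nrow(values) != nrow(design))
    stop("values has ", nrow(values), " rows but design has ", nrow(design))
  if (is.null(rownames(values))) {
    rownames(values) <- design$sample_id
  } else {
    if (!setequal(rownames(values), design$sample_id))
      stop("rownames(values) and design$sample_id do not match")
    design <- design[match(rownames(values), design$sample_id), , drop = FALSE]
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    cells <- paste0(rownames(values)[idx[, 1]], "/", colnames(values)[idx[, 2]])
    stop("missing quantification value(s) in cell(s): ",
         paste(utils::head(cells, 5L), collapse = ", "),
         if (length(cells) > 5L) " ..." else "")
  }
  if (any(values < 0))
    stop("quantifications must be nonnegative")

  tl <- unique(as.character(design$time))
  tl <- if (!anyNA(suppressWarnings(as.numeric(tl)))) {
    tl[order(as.numeric(tl))]
  } else sort(tl)
  design$individual <- factor(as.character(design$individual))
  design$time <- factor(as.character(design$time), levels = tl)
  design$condition <- factor(as.character(design$condition))

  key <- paste(design$individual, design$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual, time) observation(s): ",
         paste(unique(gsub("\r", ", ", key[duplicated(key)])), collapse = "; "))
  ic <- tapply(as.character(design$condition), design$individual,
               function(x) length(unique(x)))
  if (any(ic > 1L))
    stop("inconsistent condition for individual(s): ",
         paste(names(ic)[ic > 1L], collapse = ", "))

  ord <- order(design$time, design$individual)
  design <- design[ord, , drop = FALSE]
  rownames(design) <- NULL
  values <- values[design$sample_id, , drop = FALSE]
  structure(list(values = values, design = design), class = "quant_table")
}

#' @exportS3Method base::print
print.quant_table <- function(x, ...) {
  d <- x$design
  cat("quant_table: ", nrow(x$values), " observations x ",
      ncol(x$values), " metabolites\n", sep = "")
  cat("  individuals: ", nlevels(d$individual),
      " | time points: ", paste(levels(d$time), collapse = ", "),
      " | conditions: ", paste(levels(d$condition), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' Read a quantification table and its design from TSV files
#'
#' @param values_path TSV with header; first column `sample_id`, remaining
#'   columns metabolite quantifications.
#' @param design_path TSV with columns `sample_id`, `individual`, `time`,
#'   `condition`.
#' @return A validated [quant_table].
#' @export
read_quant_table <- function(values_path, design_path) {
  vals <- utils::read.delim(values_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(vals)[1L] != "sample_id")
    stop("first column of ", values_path, " must be 'sample_id'")
  m <- as.matrix(vals[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(vals$sample_id)
  design <- utils::read.delim(design_path, check.names = FALSE,
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  if (!setequal(rownames(m), design$sample_id))
    stop("sample ids in ", values_path, " and ", design_path, " differ")
  quant_table(m, design)
}

#' Write a quantification table to TSV files
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param qt a [quant_table].
#' @param values_path,design_path output file paths.
#' @return Invisibly, `qt`.
#' @export
write_quant_table <- function(qt, values_path, design_path) {
  stopifnot(inherits(qt, "quant_table"))
  v <- qt$values
  df <- data.frame(sample_id = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in colnames(v)) df[[j]] <- sprintf("%.17g", v[, j])
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  d <- qt$design
  d[] <- lapply(d, as.character)
  utils::write.table(d, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(qt)
}
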