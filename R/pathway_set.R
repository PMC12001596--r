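#' Pathway membership sets
#'
#' A `pathway_set` maps pathway identifiers to (possibly overlapping) sets
#' of metabolite identifiers, with an optional free-text description per
#' pathway.
#'
#' @param pathways named list of character vectors of metabolite ids.
#' @param description optional named character vector (same names).
#' @return An object of class `pathway_set`.
#' @export
pathway_set <- function(pathways, description = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("all pathways must be named")
  if (anyDuplicated(names(pathways)))
    stop("duplicate pathway id(s): ",
         paste(unique(names(pathways)[duplicated(names(pathways))]),
               collapse = ", "))
  if (any(lengths(pathways) == 0L))
    stop("empty pathway(s): ",
         paste(names(pathways)[lengths(pathways) == 0L], collapse = ", "))
  pathways <- lapply(pathways, function(x) unique(as.character(x)))
  if (is.null(description)) {
    description <- stats::setNames(rep(NA_character_, length(pathways)),
                                   names(pathways))
  } else {
    description <- description[names(pathways)]
    names(description) <- names(pathways)
  }
  structure(list(pathways = pathways, description = description),
            class = "pathway_set")
}

#' @exportS3Method base::print
print.pathway_set <- function(x, ...) {
  sz <- lengths(x$pathways)
  cat("pathway_set: ", length(sz), " pathways, sizes ",
      min(sz), "-", max(sz), " (mean ", round(mean(sz), 2), ")\n", sep = "")
  invisible(x)
}

#' @export
length.pathway_set <- function(x) length(x$pathways)

#' Read pathway membership from a GMT or long two-column TSV file
#'
#' GMT lines are `pathway_id TAB description TAB member TAB member ...`
#' (the gene-set dialect reused for metabolite sets). The long format is a
#' headered TSV of (`pathway_id`, `metabolite_id`) pairs. Members absent
#' from any particular quantification table are kept; filtering against a
#' metabolite universe happens at test time (see [filter_pathways]).
#'
#' @param path input file.
#' @param format `"gmt"` or `"long_tsv"`.
#' @return A [pathway_set].
#' @export
read_pathways <- function(path, format = c("gmt", "long_tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    desc <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
    members <- lapply(parts, function(p) {
      m <- p[-(1:2)]
      m[nzchar(m)]
    })
    bad <- ids[lengths(members) == 0L]
    if (length(bad))
      stop("pathway with no members in GMT: ", paste(bad, collapse = ", "))
    if (anyDuplicated(ids))
      stop("duplicate pathway id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    pathway_set(stats::setNames(members, ids), stats::setNames(desc, ids))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("pathway_id", "metabolite_id") %in% names(df)))
      stop("long_tsv requires columns pathway_id and metabolite_id")
    if (any(!nzchar(df$metabolite_id)))
      stop("empty metabolite_id entries in ", path)
    sp <- split(df$metabolite_id, df$pathway_id)
    # split() sorts ids; keep the file's first-appearance pathway order
    sp <- sp[unique(df$pathway_id)]
    pathway_set(sp)
  }
}

#' Write a pathway set to a GMT file
#'
#' @param ps a [pathway_set].
#' @param path output file.
#' @return Invisibly, `ps`.
#' @export
write_pathways_gmt <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_set"))
  desc <- ps$description
  desc[is.na(desc)] <- ""
  lines <- vapply(names(ps$pathways), function(id) {
    paste(c(id, desc[[id]], ps$pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(ps)
}

#' Restrict pathways to quantified metabolites
#'
#' Intersects each pathway with the metabolites present in a quantification
#' table and drops pathways with fewer than `min_size` surviving members
#' (pathways must contain at least two quantified metabolites to be
#' testable). Dropped pathways are reported in the `"dropped"` attribute.
#'
#' @param ps a [pathway_set].
#' @param qt a [quant_table] providing the metabolite universe.
#' @param min_size minimum number of surviving members (>= 2).
#' @return A filtered [pathway_set] with attribute `dropped`
#'   (data.frame: pathway_id, n_quantified).
#' @export
filter_pathways <- function(ps, qt, min_size = 2L) {
  stopifnot(inherits(ps, "pathway_set"), inherits(qt, "quant_table"))
  if (min_size < 2L) stop("min_size must be >= 2")
  universe <- colnames(qt$values)
  kept <- lapply(ps$pathways, intersect, y = universe)
  keep <- lengths(kept) >= min_size
  dropped <- data.frame(pathway_id = names(kept)[!keep],
                        n_quantified = unname(lengths(kept)[!keep]),
                        stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(nrow(dropped), " pathway(s) dropped (fewer than ", min_size,
            " quantified metabolites)")
  out <- pathway_set(kept[keep], ps$description[keep])
  attr(out, "dropped") <- dropped
  out
}
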