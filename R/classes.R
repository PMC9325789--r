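#' Construct a screen matrix
#'
#' A `screen_matrix` holds gene-by-cell-line perturbation scores from a single
#' platform (CRISPR knockout, shRNA knockdown) or from their unified
#' combination. More negative scores indicate stronger growth impairment on
#' perturbation, i.e. greater essentiality. Missing entries (`NA`) are
#' permitted.
#'
#' @param scores Numeric matrix, genes in rows, cell lines in columns.
#'   Rownames are gene symbols, colnames are cell-line identifiers; both are
#'   required and must be unique.
#' @param platform One of `"crispr"`, `"shrna"`, `"unified"`.
#' @param entrez Optional integer vector of Entrez identifiers parallel to the
#'   rows, kept as annotation only; gene identity is the symbol.
#'
#' @return An object of class `screen_matrix`: the score matrix with
#'   `platform` and `entrez` attributes.
#' @export
screen_matrix <- function(scores, platform = c("crispr", "shrna", "unified"),
                          entrez = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("'scores' must carry gene rownames and cell-line colnames")
  if (anyDuplicated(rownames(scores)))
    stop("duplicate gene symbols in screen matrix: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]), collapse = ", "))
  if (anyDuplicated(colnames(scores)))
    stop("duplicate cell-line identifiers in screen matrix")
  if (!is.null(entrez) && length(entrez) != nrow(scores))
    stop("'entrez' must have one entry per gene")
  structure(scores, platform = platform, entrez = entrez,
            class = c("screen_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> platform=%s: %d genes x %d cell lines, %d missing\n",
              attr(x, "platform"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Cell-line metadata
#'
#' Maps cell-line identifiers to lineage labels, used to partition screens
#' into a target lineage group (e.g. multiple myeloma) and a background group.
#'
#' @param line_ids Character vector of cell-line identifiers (unique).
#' @param lineage Character vector of lineage labels, parallel to `line_ids`.
#' @return A data frame of class `line_metadata` with columns `line_id`,
#'   `lineage`.
#' @export
line_metadata <- function(line_ids, lineage) {
  if (anyDuplicated(line_ids)) stop("duplicate line_ids in metadata")
  if (length(line_ids) != length(lineage))
    stop("'line_ids' and 'lineage' lengths differ")
  out <- data.frame(line_id = as.character(line_ids),
                    lineage = as.character(lineage),
                    stringsAsFactors = FALSE)
  class(out) <- c("line_metadata", "data.frame")
  out
}

#' Patient cohort with expression and survival
#'
#' Couples a gene-by-patient expression matrix to a clinical table holding
#' overall-survival (OS) and progression-free-survival (PFS) times in months,
#' event indicators, and the covariates used in adjusted Cox models: age at
#' diagnosis (years), sex, and International Staging System stage (1-3, may
#' be missing).
#'
#' @param expression Numeric matrix, genes x patients, with dimnames.
#' @param clinical Data frame with columns `patient_id`, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event`, `age`, `sex`, `iss`.
#' @param name Optional cohort label used in result tables.
#' @return A `cohort_survival` object (list with `expression`, `clinical`,
#'   `name`).
#' @export
cohort_survival <- function(expression, clinical, name = "cohort") {
  req <- c("patient_id", "os_time", "os_event", "pfs_time", "pfs_event",
           "age", "sex", "iss")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  if (!is.matrix(expression) || is.null(colnames(expression)))
    stop("'expression' must be a matrix with patient colnames")
  if (ncol(expression) != nrow(clinical))
    stop("expression has ", ncol(expression), " patients but clinical has ",
         nrow(clinical), " rows")
  if (!identical(colnames(expression), as.character(clinical$patient_id)))
    stop("expression column order must match clinical patient_id order")
  for (v in c("os_time", "pfs_time")) {
    if (any(clinical[[v]] < 0, na.rm = TRUE))
      stop("negative ", v, " in clinical table")
  }
  for (v in c("os_event", "pfs_event")) {
    if (!all(clinical[[v]] %in% c(0, 1)))
      stop(v, " must be 0/1")
  }
  if (!all(clinical$iss %in% c(1, 2, 3, NA)))
    stop("iss must be 1, 2, 3 or missing")
  structure(list(expression = expression, clinical = clinical, name = name),
            class = "cohort_survival")
}

#' @exportS3Method base::print
print.cohort_survival <- function(x, ...) {
  cat(sprintf("<cohort_survival> '%s': %d genes x %d patients (%d OS events, %d PFS events)\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$os_event), sum(x$clinical$pfs_event)))
  invisible(x)
}

#' Gene-set collection
#'
#' A named collection of gene sets (annotation terms), as read from a GMT
#' file or simulated. Member lists are de-duplicated and non-empty; term ids
#' are unique.
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param term_names Optional character vector of descriptive names, parallel
#'   to `sets`; defaults to the term ids.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, term_names = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set in collection")
  if (is.null(term_names)) term_names <- names(sets)
  if (length(term_names) != length(sets))
    stop("'term_names' must parallel 'sets'")
  structure(list(sets = sets,
                 term_names = stats::setNames(as.character(term_names), names(sets))),
            class = "gene_set_collection")
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, member sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @exportS3Method base::length
length.gene_set_collection <- function(x) length(x$sets)
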