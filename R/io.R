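#' Parse DepMap-style gene labels
#'
#' DepMap gene-effect files label columns as `"SYMBOL (ENTREZID)"`. This
#' splits the label into the symbol (the identity key) and the Entrez id,
#' which is kept as annotation only. Labels without a parenthesised id are
#' taken as bare symbols.
#'
#' @param labels Character vector of gene labels.
#' @return Data frame with columns `symbol` (character) and `entrez`
#'   (integer, `NA` where absent).
#' @export
parse_gene_label <- function(labels) {
  m <- regmatches(labels, regexec("^\\s*(\\S+)\\s*(?:\\((\\d+)\\))?\\s*$", labels))
  bad <- which(lengths(m) == 0L | vapply(m, function(x) x[2] == "", logical(1)))
  if (length(bad)) stop("unparseable gene label: ", labels[bad[1]])
  data.frame(symbol = vapply(m, `[`, "", 2),
             entrez = suppressWarnings(as.integer(vapply(m, `[`, "", 3))),
             stringsAsFactors = FALSE)
}

#' Read a DepMap-style gene-effect CSV
#'
#' Reads a perturbation-score file in the DepMap download dialect: cell lines
#' as rows (first column the line identifier), genes as the remaining column
#' headers in `"SYMBOL (ENTREZID)"` form, blank or `NA` cells denoting
#' missing scores. The matrix is transposed to genes x lines in memory so
#' per-gene operations are row-contiguous.
#'
#' @param path Path to the CSV file.
#' @param platform `"crispr"` or `"shrna"` (or `"unified"` when re-reading
#'   output of [write_screen_matrix()]).
#' @return A [screen_matrix()].
#' @export
read_screen_matrix <- function(path, platform = c("crispr", "shrna", "unified")) {
  platform <- match.arg(platform)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  if (ncol(raw) < 2L) stop("no gene columns in ", path)
  lines <- raw[[1]]
  if (anyDuplicated(lines))
    stop("duplicate cell-line identifiers in ", path, ": ",
         paste(unique(lines[duplicated(lines)]), collapse = ", "))
  genes <- parse_gene_label(names(raw)[-1])
  if (anyDuplicated(genes$symbol))
    stop("two gene columns share symbol: ",
         paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at line '%s', gene '%s'",
                 vals[bad[1, 1], bad[1, 2]], lines[bad[1, 1]],
                 genes$symbol[bad[1, 2]]))
  }
  scores <- t(num)
  dimnames(scores) <- list(genes$symbol, lines)
  screen_matrix(scores, platform = platform, entrez = genes$entrez)
}

#' Write a screen matrix in the DepMap dialect
#'
#' Inverse of [read_screen_matrix()]: cell lines as rows, genes as headers
#' (with `"SYMBOL (ENTREZID)"` labels when Entrez annotation is present),
#' missing values as empty cells. Values are written with full double
#' precision so a read/write round trip preserves scores to better than 1e-9
#' relative error.
#'
#' @param x A [screen_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_matrix <- function(x, path) {
  stopifnot(inherits(x, "screen_matrix"))
  entrez <- attr(x, "entrez")
  labels <- if (is.null(entrez)) rownames(x) else
    ifelse(is.na(entrez), rownames(x), sprintf("%s (%d)", rownames(x), entrez))
  out <- t(unclass(x))
  df <- data.frame(line_id = rownames(out),
                   format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("line_id", labels)
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read cell-line metadata
#'
#' @param path CSV with columns `line_id` and `lineage` (extra columns are
#'   ignored).
#' @return A [line_metadata()] data frame.
#' @export
read_line_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "lineage") %in% names(df)))
    stop("metadata file needs 'line_id' and 'lineage' columns")
  line_metadata(df$line_id, df$lineage)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate member
#' genes within a term are de-duplicated.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) stop("no terms in ", path)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, term_names = vapply(fields, `[`, "", 2))
}

#' Write a gene-set collection as GMT
#'
#' @param x A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$term_names[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a patient cohort (expression + clinical)
#'
#' Reads a genes x samples expression table (TSV or CSV, inferred from the
#' extension; first column gene symbol) and a clinical CSV with columns
#' `patient_id`, `os_time`, `os_event`, `pfs_time`, `pfs_event`, `age`,
#' `sex`, `iss`. The two are inner-joined on patient id; patients present in
#' only one table are dropped with a message giving the count. ISS may be
#' blank (retained as `NA`).
#'
#' @param expr_path Expression matrix path.
#' @param clinical_path Clinical table path.
#' @param name Cohort label.
#' @return A [cohort_survival()].
#' @export
read_cohort <- function(expr_path, clinical_path, name = basename(expr_path)) {
  sep <- if (grepl("\\.tsv$|\\.txt$", expr_path)) "\t" else ","
  edf <- utils::read.table(expr_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(edf[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- edf[[1]]
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  clin$patient_id <- as.character(clin$patient_id)
  common <- intersect(colnames(expr), clin$patient_id)
  if (!length(common))
    stop("zero overlapping patients between expression and clinical tables")
  dropped <- (ncol(expr) - length(common)) + (nrow(clin) - length(common))
  if (dropped > 0)
    message("read_cohort: dropped ", dropped,
            " patient(s) absent from one of the two tables")
  clin <- clin[match(common, clin$patient_id), , drop = FALSE]
  rownames(clin) <- NULL
  cohort_survival(expr[, common, drop = FALSE], clin, name = name)
}
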