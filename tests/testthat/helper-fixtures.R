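# In-code fixtures: tiny files written to tempdir() at test time.

write_depmap_csv <- function(lines, gene_labels, values, path = tempfile(fileext = ".csv")) {
  # values: line x gene matrix (file dialect), NA -> blank
  df <- data.frame(DepMap_ID = lines, values, check.names = FALSE)
  names(df) <- c("DepMap_ID", gene_labels)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

write_gmt_lines <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# a small complete screen pair on a shared grid, as screen_matrix objects
toy_screens <- function(n_genes = 60, n_lines = 6, seed = 42, sd = 0.3) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  lines <- sprintf("L%02d", seq_len(n_lines))
  latent <- matrix(rnorm(n_genes * n_lines, -0.5, 1), n_genes, n_lines,
                   dimnames = list(genes, lines))
  list(crispr = screen_matrix(latent + rnorm(n_genes * n_lines, 0, sd), "crispr"),
       shrna = screen_matrix(latent + rnorm(n_genes * n_lines, 0, sd), "shrna"))
}

write_cohort_files <- function(cohort, dir = tempfile()) {
  dir.create(dir)
  expr_path <- file.path(dir, "expr.tsv")
  df <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", row.names = FALSE, quote = FALSE)
  clin_path <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, clin_path, row.names = FALSE, na = "")
  list(expr = expr_path, clinical = clin_path)
}
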