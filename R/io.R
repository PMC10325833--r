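#' Read an abundance table from TSV or BIOM
#'
#' The TSV dialect is the common QIIME export: tab-separated, UTF-8, lines
#' starting with `#` ignored, taxa as rows with the taxon id in the first
#' column, samples as the remaining columns, and an optional final
#' `taxonomy` column of semicolon-delimited lineages. Orientation is
#' auto-detected from the header sentinel (a first header field of
#' `sample_id`/`sample`/`samples` flips to samples-as-rows) and can be
#' overridden. Files ending in `.biom` are read through the biomformat
#' package (read-only).
#'
#' @param path Path to a `.tsv`/`.txt` or `.biom` file.
#' @param site,mode Passed to [abundance_table()].
#' @param orientation `"auto"` (header sentinel), `"taxa_rows"` or
#'   `"samples_rows"`.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path, site = c("gut", "oral", "other"),
                           mode = c("counts", "relative"),
                           orientation = c("auto", "taxa_rows", "samples_rows")) {
  site <- match.arg(site)
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    return(abundance_table(t(m), site = site, mode = mode))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  first <- tolower(names(df)[1])
  taxa_rows <- switch(orientation,
                      taxa_rows = TRUE,
                      samples_rows = FALSE,
                      auto = !(first %in% c("sample_id", "sample", "samples")))
  message(sprintf("read_abundance: %s read as %s", basename(path),
                  if (taxa_rows) "taxa-as-rows" else "samples-as-rows"))
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated id(s) in first column: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    if (taxa_rows) {
      taxonomy <- stats::setNames(as.character(df[[ncol(df)]]), ids)
      taxonomy <- taxonomy[!is.na(taxonomy) & nzchar(taxonomy)]
    }
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path,
                           call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (taxa_rows) m <- t(m)
  abundance_table(m, site = site, mode = mode, taxonomy = taxonomy)
}

#' Write an abundance table as TSV
#'
#' Taxa as rows (first column `taxon_id`), samples as columns, optional
#' trailing `taxonomy` column; the exact dialect [read_abundance()] reads.
#'
#' @param table An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  m <- t(table$values) # taxa x samples
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) {
    df$taxonomy <- unname(table$taxonomy[df$taxon_id])
    df$taxonomy[is.na(df$taxonomy)] <- ""
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject-sample pairing from per-site TSV files
#'
#' Each file has two columns, `subject_id` and `sample_id`.
#'
#' @param gut_path,oral_path Paths to the per-site pairing TSVs.
#' @return Long-format data frame with columns `subject_id`, `site`,
#'   `sample_id`, suitable for [align_pairs()].
#' @export
read_pairing <- function(gut_path, oral_path) {
  rd <- function(p, site) {
    df <- utils::read.delim(p, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("subject_id", "sample_id") %in% names(df))) {
      stop("pairing file needs columns subject_id and sample_id: ", p,
           call. = FALSE)
    }
    data.frame(subject_id = as.character(df$subject_id), site = site,
               sample_id = as.character(df$sample_id),
               stringsAsFactors = FALSE)
  }
  rbind(rd(gut_path, "gut"), rd(oral_path, "oral"))
}
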