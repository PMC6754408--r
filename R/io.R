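# Containers and tab-delimited I/O for the tables every analysis step consumes.
#
# Genomic coordinates in OCR tables are 0-based half-open (BED convention)
# throughout the package.

#' Expression matrix container
#'
#' Bundles a genes x samples numeric matrix with per-gene annotation and a
#' scale flag. Values on the `log2` scale must be finite; values on the
#' `counts` or `linear` scale must be non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   (or `gene_ids`) identify genes; column names (or `sample_ids`) identify
#'   samples.
#' @param gene_ids,sample_ids Optional identifier vectors overriding dimnames.
#' @param gene_symbols Optional per-gene symbols (defaults to the ids).
#' @param gene_chromosome Optional per-gene chromosome labels (autosome name,
#'   `"X"`, `"Y"`, or `NA` for unknown).
#' @param scale One of `"counts"`, `"linear"`, `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (matrix), `genes` (tibble: gene_id, symbol, chromosome) and `scale`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values),
                        gene_symbols = gene_ids, gene_chromosome = NULL,
                        scale = c("log2", "linear", "counts")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(gene_ids)) stop("gene ids are required (row names or gene_ids)")
  if (is.null(sample_ids)) stop("sample ids are required (column names or sample_ids)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  storage.mode(values) <- "double"
  if (scale == "log2" && any(!is.finite(values))) {
    stop("log2-scale expression values must be finite")
  }
  if (scale != "log2" && any(values < 0, na.rm = TRUE)) {
    stop("counts/linear-scale expression values must be non-negative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  genes <- tibble(
    gene_id = gene_ids,
    symbol = as.character(gene_symbols %||% gene_ids),
    chromosome = if (is.null(gene_chromosome)) NA_character_ else as.character(gene_chromosome)
  )
  structure(list(values = values, genes = genes, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' OCR accessibility table container
#'
#' @param values Numeric matrix, OCRs x samples, normalized log2 accessibility.
#' @param ranges Data frame with columns `ocr_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `annotation_class` (one of `"TSS"`, `"gene_body"`,
#'   `"distal_enhancer"`, `"other"`) and `associated_gene` (symbol or `NA`).
#' @return An object of class `ocr_table`.
#' @export
ocr_table <- function(values, ranges) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ranges <- as_tibble(ranges)
  needed <- c("ocr_id", "chrom", "start", "end", "annotation_class", "associated_gene")
  missing_cols <- setdiff(needed, names(ranges))
  if (length(missing_cols)) stop("ranges is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(ranges) != nrow(values)) stop("ranges and values disagree on OCR count")
  if (anyDuplicated(ranges$ocr_id)) stop("duplicate ocr_id values")
  if (any(ranges$start >= ranges$end)) {
    bad <- ranges$ocr_id[ranges$start >= ranges$end]
    stop("start >= end for OCR(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("accessibility values must be finite")
  known <- c("TSS", "gene_body", "distal_enhancer", "other")
  unknown <- !(ranges$annotation_class %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " OCR(s) with unknown annotation_class mapped to 'other'")
    ranges$annotation_class[unknown] <- "other"
  }
  ranges <- ranges[c(needed, setdiff(names(ranges), needed))]
  rownames(values) <- ranges$ocr_id
  structure(list(values = values, ranges = ranges), class = "ocr_table")
}

#' @export
print.ocr_table <- function(x, ...) {
  cat(sprintf("<ocr_table> %d OCRs x %d samples\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a gene x sample expression table
#'
#' Tab-delimited with a header line; first column is the gene id, optional
#' `symbol` and `chromosome` columns follow, all remaining columns are
#' per-sample numeric values. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param scale Scale flag of the stored values (see [expr_matrix()]).
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, scale = c("log2", "linear", "counts")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) stop("format error: expected a header with gene id and sample columns")
  ids <- df[[1]]
  df <- df[-1]
  symbols <- NULL
  chroms <- NULL
  if ("symbol" %in% names(df)) {
    symbols <- df[["symbol"]]
    df[["symbol"]] <- NULL
  }
  if ("chromosome" %in% names(df)) {
    chroms <- df[["chromosome"]]
    df[["chromosome"]] <- NULL
  }
  vals <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(ids, names(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: non-numeric value at row %d (gene %s), column '%s'",
                 bad[1], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  expr_matrix(vals, gene_ids = ids, gene_symbols = symbols %||% ids,
              gene_chromosome = chroms, scale = scale)
}

#' Write an expression table
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @param provenance Optional character vector written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- tibble(gene_id = x$genes$gene_id,
               symbol = x$genes$symbol,
               chromosome = x$genes$chromosome)
  df <- dplyr::bind_cols(df, as_tibble(x$values))
  write_with_comments(df, path, provenance)
  invisible(path)
}

write_with_comments <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, format_field), sep = "\t"))
  if (length(body)) writeLines(body, con)
}

format_field <- function(col) {
  if (is.double(col)) {
    out <- formatC(col, digits = 17, format = "g")
  } else {
    out <- as.character(col)
  }
  out[is.na(col)] <- ""
  out
}

#' Read sample metadata
#'
#' Tab-delimited with required columns `sample_id` and `sex`; sex values are
#' normalized case-insensitively from \{F, M, female, male\} to \{F, M\}.
#' Optional factor columns (`cell_type`, `dataset`, `age_group`, `tissue`,
#' `stimulation`, `replicate`, ...) are preserved.
#'
#' @param path File path.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_metadata(df)
}

#' Validate and normalize a sample-metadata table
#'
#' @param df Data frame with at least `sample_id` and `sex`.
#' @return The normalized tibble.
#' @export
validate_metadata <- function(df) {
  df <- as_tibble(df)
  if (!all(c("sample_id", "sex") %in% names(df))) {
    stop("metadata must contain columns 'sample_id' and 'sex'")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  sex <- toupper(as.character(df$sex))
  sex[sex == "FEMALE"] <- "F"
  sex[sex == "MALE"] <- "M"
  bad <- !(sex %in% c("F", "M"))
  if (any(bad)) {
    stop("invalid sex value(s): ", paste(unique(df$sex[bad]), collapse = ", "))
  }
  df$sex <- sex
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write sample metadata
#' @param df Metadata tibble.
#' @param path Output path.
#' @param provenance Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(df, path, provenance = NULL) {
  write_with_comments(validate_metadata(df), path, provenance)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' MSigDB dialect: one set per line, `name TAB description TAB gene1 TAB ...`;
#' trailing empty fields are dropped.
#'
#' @param path File path.
#' @return An object of class `gene_sets`: a list with `sets` (named list of
#'   character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descr <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop(sprintf("format error in GMT line %d: fewer than 3 non-empty fields", i))
    }
    nm <- fields[[1]]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    sets[[nm]] <- fields[-(1:2)]
    descr[[nm]] <- fields[[2]]
  }
  gene_sets(sets, descr)
}

#' Gene-set collection constructor
#' @param sets Named list of character vectors (no empty set).
#' @param description Optional named descriptions.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("all gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  if (any(lengths(sets) == 0)) stop("empty gene set: ",
                                    paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  description <- description %||% setNames(rep("na", length(sets)), names(sets))
  structure(list(sets = lapply(sets, as.character),
                 description = description[names(sets)]),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Write a gene-set collection in GMT format
#' @param x A `gene_sets` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OCR accessibility table
#'
#' BED-like leading columns (`chrom`, `start`, `end`, `ocr_id`,
#' `annotation_class`, `associated_gene`) followed by per-sample numeric
#' columns of normalized log2 accessibility. Coordinates are 0-based
#' half-open. Unknown annotation classes are mapped to `"other"` with a
#' warning.
#'
#' @param path File path.
#' @return An [ocr_table()].
#' @export
read_ocr_table <- function(path) {
  # read everything as character and convert with as.numeric/as.integer:
  # base conversion round-trips doubles written with 17 significant digits
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  lead <- c("chrom", "start", "end", "ocr_id", "annotation_class", "associated_gene")
  missing_cols <- setdiff(lead, names(df))
  if (length(missing_cols)) stop("OCR table missing columns: ", paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), lead)
  if (!length(sample_cols)) stop("OCR table has no sample columns")
  vals <- matrix(as.numeric(as.matrix(df[sample_cols])), nrow = nrow(df),
                 dimnames = list(NULL, sample_cols))
  if (anyNA(vals)) stop("non-numeric accessibility value in OCR table")
  ranges <- df[lead]
  ranges$start <- as.integer(ranges$start)
  ranges$end <- as.integer(ranges$end)
  ranges$associated_gene <- as.character(ranges$associated_gene)
  ocr_table(vals, ranges)
}

#' Write an OCR accessibility table
#' @param x An [ocr_table()].
#' @param path Output path.
#' @param provenance Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_ocr_table <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "ocr_table"))
  df <- dplyr::bind_cols(
    x$ranges[c("chrom", "start", "end", "ocr_id", "annotation_class", "associated_gene")],
    as_tibble(x$values)
  )
  write_with_comments(df, path, provenance)
  invisible(path)
}
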