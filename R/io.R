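#' Read a log2 expression matrix from TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Duplicate gene ids are collapsed to the row with the highest mean
#' expression (the usual microarray probe-collapse convention); a message is
#' emitted naming how many rows were dropped.
#'
#' @param path Path to a tab-separated file, UTF-8, `.` decimal.
#' @param scale Either `"log2"` (default) or `"linear"`; stored as an
#'   attribute on the returned matrix.
#' @return A numeric matrix (genes x samples) with unique rownames and
#'   colnames and attribute `scale`.
#' @export
read_expression <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty expression matrix in '", path, "'")
  }
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene row %d ('%s'), sample column '%s'",
                 bad[1, 1], gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  na_cells <- which(is.na(num), arr.ind = TRUE)
  if (nrow(na_cells)) {
    stop(sprintf("missing value at gene row %d ('%s'), sample column '%s'; imputation is not performed",
                 na_cells[1, 1], gene_ids[na_cells[1, 1]],
                 colnames(num)[na_cells[1, 2]]))
  }
  rownames(num) <- gene_ids
  num <- collapse_duplicate_genes(num)
  validate_expression(num)
  attr(num, "scale") <- scale
  num
}

# keep, per duplicated id, the row with the highest mean expression
collapse_duplicate_genes <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  rm <- rowMeans(x)
  keep <- unlist(lapply(split(seq_len(nrow(x)), rownames(x)),
                        function(idx) idx[which.max(rm[idx])]))
  dropped <- nrow(x) - length(keep)
  message(dropped, " duplicated gene id row(s) collapsed by max-mean rule")
  x[sort(keep), , drop = FALSE]
}

validate_expression <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x)) stop("missing values in expression matrix")
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotations from TSV
#'
#' Expected columns: `sample_id`, `batch`, `condition` (IBD/healthy), and
#' optionally `disease` (UC/CD) and `response` (responder/non-responder).
#'
#' @param path Path to a tab-separated annotation file.
#' @return A data.frame with one row per sample.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  req <- c("sample_id", "batch", "condition")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(ann$batch)) || anyNA(ann$batch)) stop("empty batch labels")
  bad <- setdiff(unique(ann$condition), c("IBD", "healthy"))
  if (length(bad)) stop("unknown condition value(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(ann$disease)) ann$disease <- NA_character_
  if (is.null(ann$response)) ann$response <- NA_character_
  ann
}

#' Write sample annotations to TSV
#' @param ann Annotation data.frame (see [read_annotations()]).
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are dropped; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  empty <- !vapply(sets, length, 1L)
  if (any(empty)) stop("gene set with no members: ", nm[empty][1])
  descr <- vapply(fields, `[[`, "", 2L)
  names(descr) <- nm
  attr(sets, "descriptions") <- descr
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors; optional attribute
#'   `descriptions`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  descr <- attr(sets, "descriptions")
  if (is.null(descr)) descr <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descr[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an OTU/taxon count table from TSV
#'
#' Expected columns: `taxon_id`, `lineage` (semicolon-separated ranks
#' `k__;p__;c__;o__;f__;g__`), then one integer count column per sample.
#' Taxa whose lineage lacks the genus rank are retained and flagged
#' unclassified at genus.
#'
#' @param path Path to a tab-separated count table.
#' @return An object of class `OtuTable`: list with `counts` (taxa x samples
#'   integer matrix) and `lineage` (character vector).
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  req <- c("taxon_id", "lineage")
  if (!all(req %in% names(df))) {
    stop("OTU table must have 'taxon_id' and 'lineage' columns")
  }
  counts <- as.matrix(df[, setdiff(names(df), req), drop = FALSE])
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("negative count in OTU table")
  if (any(counts != floor(counts))) stop("fractional count in OTU table")
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$taxon_id
  lineage <- df$lineage
  no_genus <- !grepl("g__[^;]+", lineage)
  if (any(no_genus)) {
    lineage[no_genus] <- sub("(g__)?$", "g__unclassified", lineage[no_genus])
    message(sum(no_genus), " taxa flagged unclassified at genus rank")
  }
  otu_table(counts, lineage)
}

#' Construct an OtuTable
#' @param counts Nonnegative integer taxa x samples matrix with dimnames.
#' @param lineage Character vector of lineage strings, one per taxon.
#' @return An `OtuTable` object.
#' @export
otu_table <- function(counts, lineage) {
  stopifnot(is.matrix(counts), nrow(counts) == length(lineage))
  if (any(counts < 0)) stop("counts must be nonnegative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  structure(list(counts = counts, lineage = lineage), class = "OtuTable")
}

#' Write an OtuTable to TSV
#' @param otu An `OtuTable`.
#' @param path Output path.
#' @export
write_otu_table <- function(otu, path) {
  df <- data.frame(taxon_id = rownames(otu$counts), lineage = otu$lineage,
                   otu$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an immune-cell signature matrix from TSV
#'
#' Layout as [read_expression()] (genes in rows, cell types in columns).
#'
#' @param path Path to a tab-separated signature matrix.
#' @return A nonnegative numeric matrix genes x cell types.
#' @export
read_signature <- function(path) {
  s <- read_expression(path, scale = "linear")
  attr(s, "scale") <- NULL
  if (any(colSums(s != 0) == 0)) {
    stop("signature matrix has an all-zero cell-type column")
  }
  s
}
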