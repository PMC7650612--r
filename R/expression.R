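#' @include AllClasses.R
NULL

.WEIGHT_LOWER <- 0.1
.WEIGHT_UPPER <- 100

.idSymbolCache <- new.env(parent = emptyenv())

#' Packaged Ensembl-id to gene-symbol table
#'
#' Covers the gene families of the reduced ErbB fixture and the 19 species
#' of the full ErbB pathway mapping. Ids appear without version suffixes;
#' lookups strip versions before matching.
#'
#' @return named character vector, Ensembl gene id -> symbol.
#' @export
geneIdSymbolTable <- function() {
  if (!is.null(.idSymbolCache$tab)) return(.idSymbolCache$tab)
  path <- system.file("extdata", "gene_id_symbol.tsv", package = "sigdyn",
                      mustWork = TRUE)
  df <- readTsv(path)
  tab <- setNames(df$symbol, df$gene_id)
  .idSymbolCache$tab <- tab
  tab
}

#' Read a TPM expression table
#'
#' Two tab-separated dialects are supported, both gzip-transparent and
#' requiring a header row:
#' \describe{
#'   \item{`plain`}{first column gene symbol, remaining columns one per
#'     cell line.}
#'   \item{`ccle`}{CCLE-RSEM-like: first column Ensembl gene id (an
#'     optional `.NN` version suffix is stripped), second column transcript
#'     ids (ignored), remaining columns samples. Gene ids are translated
#'     to symbols through the packaged id table ([geneIdSymbolTable()]);
#'     unmapped ids are retained under their raw (version-stripped) id.}
#' }
#' Ragged rows, missing headers, non-numeric or negative values raise a
#' parse error naming the offending line. Duplicate gene symbols after id
#' resolution are an error listing the symbols.
#'
#' @param path file path (optionally gzip-compressed).
#' @param dialect `"plain"` or `"ccle"`.
#' @return an [ExpressionTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_symbol\tA\tB", "EGFR\t10\t20", "ERBB3\t5\t2"), f)
#' readExpressionTable(f, "plain")
#' @export
readExpressionTable <- function(path, dialect = c("plain", "ccle")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 2L)
    stop("expression table needs a header row and at least one gene row",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol <- length(header)
  nmeta <- if (dialect == "ccle") 2L else 1L
  if (ncol < nmeta + 1L)
    stop("parse error at line 1: header has too few columns", call. = FALSE)

  nGenes <- length(lines) - 1L
  ids <- character(nGenes)
  vals <- matrix(NA_real_, nGenes, ncol - nmeta)
  for (i in seq_len(nGenes)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncol)
      stop(sprintf("parse error at line %d: expected %d columns, found %d",
                   i + 1L, ncol, length(row)), call. = FALSE)
    ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[(nmeta + 1L):ncol]))
    if (any(is.na(v)))
      stop(sprintf("parse error at line %d: non-numeric TPM value", i + 1L),
           call. = FALSE)
    if (any(v < 0))
      stop(sprintf("parse error at line %d: negative TPM value", i + 1L),
           call. = FALSE)
    vals[i, ] <- v
  }

  if (dialect == "ccle") {
    stripped <- sub("\\.[0-9]+$", "", ids)
    tab <- geneIdSymbolTable()
    sym <- unname(tab[stripped])
    sym[is.na(sym)] <- stripped[is.na(sym)]
  } else {
    sym <- ids
  }
  if (anyDuplicated(sym))
    stop("duplicate gene symbol(s) after resolution: ",
         paste(unique(sym[duplicated(sym)]), collapse = ", "),
         call. = FALSE)
  rownames(vals) <- sym
  colnames(vals) <- header[(nmeta + 1L):ncol]
  expressionTable(vals)
}

#' Write an ExpressionTable
#'
#' The `plain` dialect round-trips exactly through
#' [readExpressionTable()]. The `ccle` dialect writes Ensembl ids (with a
#' `.1` version suffix) where the packaged table knows the symbol, plus a
#' placeholder transcript-id column.
#'
#' @param x an [ExpressionTable-class].
#' @param path output path (`.gz` suffix writes gzip).
#' @param dialect `"plain"` or `"ccle"`.
#' @return the path, invisibly.
#' @export
writeExpressionTable <- function(x, path, dialect = c("plain", "ccle")) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "ExpressionTable"))
  m <- tpmMatrix(x)
  fmt <- function(v) sprintf("%.15g", v)
  if (dialect == "plain") {
    lines <- c(paste(c("gene_symbol", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"),
                 character(1)))
  } else {
    tab <- geneIdSymbolTable()
    rev <- setNames(names(tab), tab)
    ids <- unname(rev[rownames(m)])
    ids[!is.na(ids)] <- paste0(ids[!is.na(ids)], ".1")
    ids[is.na(ids)] <- rownames(m)[is.na(ids)]
    lines <- c(paste(c("gene_id", "transcript_ids", colnames(m)),
                     collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(ids[i], "NA", fmt(m[i, ])), collapse = "\t"),
                 character(1)))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Sum gene-family TPM per model species for one cell line
#'
#' Implements the isoform-summation rule: the inferred amount of a species
#' is the sum of the TPM values of its mapped gene-family members.
#'
#' @param table an [ExpressionTable-class].
#' @param mapping a [GeneMapping-class].
#' @param cellLine cell-line id (column of `table`).
#' @return named numeric, summed TPM per species.
#' @examples
#' m <- matrix(c(2, 3, 0), 3, 1,
#'             dimnames = list(c("AKT1", "AKT2", "AKT3"), "A"))
#' extractGenes(expressionTable(m), geneMapping(list(
#'   Akt = c("AKT1", "AKT2", "AKT3"))), "A")
#' @export
extractGenes <- function(table, mapping, cellLine) {
  stopifnot(is(table, "ExpressionTable"), is(mapping, "GeneMapping"))
  if (!cellLine %in% cellLineIds(table))
    stop("cell line not in expression table: ", cellLine, call. = FALSE)
  m <- tpmMatrix(table)
  vapply(names(mapping@mapping), function(sp) {
    genes <- mapping@mapping[[sp]]
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop(sprintf("species '%s': gene symbol(s) absent from table: %s",
                   sp, paste(missing, collapse = ", ")), call. = FALSE)
    sum(m[genes, cellLine])
  }, numeric(1))
}

#' Build model initial values from summed TPM and weighting factors
#'
#' Converts expression to initial amounts as `weight x summed TPM` per
#' expression-initialized species and delegates to the model's initial
#' builder: conserved totals are set from the amounts, every
#' active/phosphorylated species starts at 0, and non-expression species
#' keep their model-declared defaults. Weighting factors are dimensionless,
#' shared across cell lines, and must lie within the configured search
#' bounds `[0.1, 100]`.
#'
#' @param summedTpm named numeric, summed TPM per species (from
#'   [extractGenes()]).
#' @param weights numeric weighting factors, either named by species or in
#'   the order of `summedTpm`.
#' @param model a [ReactionModel-class].
#' @param params named kinetic/parameter vector to thread the totals into.
#' @return list with `params` (updated parameter vector), `state` (initial
#'   state vector) and `amounts` (the weighted amounts used).
#' @export
buildInitialValues <- function(summedTpm, weights, model, params) {
  checkNamedNumeric(summedTpm, "summedTpm")
  if (is.null(names(weights))) {
    if (length(weights) != length(summedTpm))
      stop("unnamed weights must match summedTpm in length", call. = FALSE)
    weights <- setNames(as.numeric(weights), names(summedTpm))
  }
  missing <- setdiff(names(summedTpm), names(weights))
  if (length(missing))
    stop("no weighting factor for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  weights <- weights[names(summedTpm)]
  bad <- weights < .WEIGHT_LOWER | weights > .WEIGHT_UPPER
  if (any(bad))
    stop(sprintf("weighting factor(s) outside the configured bounds [%g, %g]: %s",
                 .WEIGHT_LOWER, .WEIGHT_UPPER,
                 paste(names(weights)[bad], collapse = ", ")),
         call. = FALSE)
  amounts <- weights * summedTpm
  out <- model@initialBuilder(params, amounts)
  out$amounts <- amounts
  out
}

#' Packaged gene mapping of the 19-species ErbB pathway model
#'
#' Species-to-gene-family mapping for the full ErbB signaling model
#' (receptors, adaptors, Ras/MAPK tier, Akt branch and nuclear effectors),
#' using standard family members; user-overridable by constructing a
#' [GeneMapping-class] directly or via [readGeneMapping()].
#'
#' @return a [GeneMapping-class] with 19 species entries.
#' @examples
#' length(speciesGenes(erbbPathwayMapping()))
#' @export
erbbPathwayMapping <- function() {
  path <- system.file("extdata", "mapping_erbb19.tsv", package = "sigdyn",
                      mustWork = TRUE)
  readGeneMapping(path)
}

#' Read a species-to-genes mapping file
#'
#' Two-column TSV with header `species`, `genes`; the second column is a
#' comma-separated list of gene symbols.
#'
#' @param path mapping file path.
#' @return a [GeneMapping-class].
#' @export
readGeneMapping <- function(path) {
  df <- readTsv(path)
  if (!all(c("species", "genes") %in% names(df)))
    stop("mapping file must have columns species, genes", call. = FALSE)
  geneMapping(setNames(lapply(strsplit(df$genes, ","), trimws),
                       df$species))
}
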