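#' @useDynLib tpsurvey, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim rbinom rnbinom runif rnorm sd t.test
#'   setNames quantile
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

# ---------------------------------------------------------------------------
# Coordinate conventions: every coordinate in this package is 1-based and
# inclusive at both ends. BED input (0-based, half-open) is converted on read.
# ---------------------------------------------------------------------------

#' Length of a 1-based inclusive interval
#'
#' @param start,end integer coordinates, 1-based inclusive, `start <= end`.
#' @return `end - start + 1` (bp or residues).
#' @examples
#' span_length(73878251, 73885160)  # 6910, a typical maize LTR element
#' @export
span_length <- function(start, end) {
  if (any(start < 1) || any(end < 1)) {
    stop("coordinates must be positive (1-based)")
  }
  if (any(start > end)) stop("start must not exceed end")
  end - start + 1
}

#' Sequence records
#'
#' A `tps_seqs` object is a named character vector of residue strings with a
#' `description` attribute and an `alphabet` attribute (`"protein"` or
#' `"dna"`). IDs must be unique and non-empty; residues are stored uppercase.
#'
#' @param residues named character vector of sequences.
#' @param description optional character vector of per-record descriptions.
#' @param alphabet `"protein"` or `"dna"`.
#' @return a `tps_seqs` object.
#' @export
tps_seqs <- function(residues, description = NULL, alphabet = "protein") {
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids))) stop("every record needs a non-empty id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(residues))) stop("empty sequence for id(s): ",
                                   paste(ids[!nzchar(residues)], collapse = ", "))
  alphabet <- match.arg(alphabet, c("protein", "dna"))
  residues <- toupper(residues)
  ok <- if (alphabet == "protein") {
    grepl("^[ARNDCQEGHILKMFPSTWYVXBZJUO*]+$", residues)
  } else {
    grepl("^[ACGTUNRYSWKMBDHV]+$", residues)
  }
  if (!all(ok)) stop("residues outside the ", alphabet, " alphabet in: ",
                     paste(ids[!ok], collapse = ", "))
  structure(residues,
            description = description %||% rep("", length(residues)),
            alphabet = alphabet, class = "tps_seqs")
}

#' @export
print.tps_seqs <- function(x, ...) {
  cat("tps_seqs: ", length(x), " ", attr(x, "alphabet"), " sequence(s), ",
      "lengths ", min(nchar(x)), "-", max(nchar(x)), "\n", sep = "")
  invisible(x)
}

#' @export
`[.tps_seqs` <- function(x, i) {
  tps_seqs(unclass(x)[i], description = attr(x, "description")[i],
           alphabet = attr(x, "alphabet"))
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()]; residues are uppercased, the first
#' whitespace-delimited token of each header is the id, the remainder the
#' description. Duplicate ids or empty sequences are format errors.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @return a [tps_seqs] object.
#' @export
read_fasta <- function(path, alphabet = "protein") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no records in ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(ss)
  names(seqs) <- ids
  tps_seqs(seqs, description = desc, alphabet = alphabet)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` recovers `x`.
#'
#' @param seqs a [tps_seqs] object or named character vector.
#' @param path output file.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  desc <- attr(seqs, "description") %||% rep("", length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    header <- if (nzchar(desc[i])) paste(names(seqs)[i], desc[i]) else names(seqs)[i]
    writeLines(paste0(">", header), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Genome annotation: ordered gene models per chromosome
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and optionally `coding_length` (defaults to the gene span).
#' @param species species label.
#' @param genome_size assembly size in bp; defaults to the maximum gene end.
#' @return a `genome_annotation`: list with `species`, `genome_size` and a
#'   `genes` data.frame carrying a 1-based `rank` per chromosome (ordered by
#'   start, ties broken by `gene_id`).
#' @export
genome_annotation <- function(genes, species = "synthetic", genome_size = NULL) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genes must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be globally unique")
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (is.null(genes$coding_length)) {
    genes$coding_length <- genes$end - genes$start + 1
  }
  if (any(genes$coding_length > genes$end - genes$start + 1)) {
    stop("coding_length exceeds gene span")
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$chrom, FUN = seq_along))
  rownames(genes) <- NULL
  genome_size <- genome_size %||% max(genes$end)
  if (genome_size < max(genes$end)) stop("genome_size smaller than last gene end")
  structure(list(species = species, genome_size = genome_size, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation: ", x$species, ", ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chrom)), " chromosome(s), genome ",
      x$genome_size, " bp\n", sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of type `gene` (configurable); the gene id is taken from the
#' `ID=` attribute. Ranks are assigned per chromosome by start coordinate.
#'
#' @param path GFF3 file.
#' @param species species label for the annotation.
#' @param genome_size optional assembly size (bp).
#' @param feature_type feature type to keep (default `"gene"`).
#' @return a [genome_annotation].
#' @export
read_gff_genes <- function(path, species = "synthetic", genome_size = NULL,
                           feature_type = "gene") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no features in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9)) stop("malformed GFF3 (expected 9 columns)")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == feature_type
  if (!any(keep)) stop("no '", feature_type, "' features in ", path)
  m <- m[keep, , drop = FALSE]
  attr_id <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
  genes <- data.frame(gene_id = attr_id, chrom = m[, 1],
                      start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                      strand = m[, 7], stringsAsFactors = FALSE)
  genome_annotation(genes, species = species, genome_size = genome_size)
}

#' Write gene models to GFF3
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(annotation, path, source = "tpsurvey") {
  g <- annotation$genes
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, source, g$start, g$end, g$strand, g$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read feature intervals from BED or GFF3
#'
#' BED is 0-based half-open and converted to this package's 1-based inclusive
#' convention on read (`start + 1`, `end` unchanged). The BED name column (or
#' GFF3 type column) becomes `feature_type`.
#'
#' @param path BED or GFF3 file; format chosen by extension unless `format`
#'   is given.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `feature_type`
#'   (1-based inclusive).
#' @export
read_elements <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), feature_type = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(max(lengths(fields)))]))
  if (format == "bed") {
    data.frame(chrom = m[, 1], start = as.integer(m[, 2]) + 1L,
               end = as.integer(m[, 3]),
               feature_type = if (ncol(m) >= 4) m[, 4] else "feature",
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = m[, 1], start = as.integer(m[, 4]),
               end = as.integer(m[, 5]), feature_type = m[, 3],
               stringsAsFactors = FALSE)
  }
}

#' Write feature intervals to BED
#'
#' Converts from 1-based inclusive back to BED's 0-based half-open convention.
#'
#' @param elements data.frame with `chrom`, `start`, `end`, `feature_type`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", elements$chrom,
                     elements$start - 1L, elements$end, elements$feature_type),
             path)
  invisible(path)
}

#' Read an expression matrix with its sample design
#'
#' @param counts_path TSV: first column gene ids, remaining columns samples.
#' @param design_path TSV with columns `sample`, `tissue`, `replicate`.
#' @param mode `"counts"` (raw counts) or `"normalized"` (e.g. microarray
#'   values used as-is, skipping FPKM).
#' @param gene_lengths optional named vector of transcript lengths (bp),
#'   required later for FPKM in counts mode.
#' @return an `expression_table`: list with `values` (gene x sample matrix),
#'   `design` (data.frame), `mode`, `gene_lengths`.
#' @export
read_expression <- function(counts_path, design_path, mode = c("counts", "normalized"),
                            gene_lengths = NULL) {
  mode <- match.arg(mode)
  tab <- read.delim(counts_path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  expression_table(values, design, mode = mode, gene_lengths = gene_lengths)
}

#' Construct an expression table
#'
#' @param values gene x sample numeric matrix with dimnames.
#' @param design data.frame with `sample`, `tissue`, `replicate`; samples must
#'   match `colnames(values)`.
#' @param mode `"counts"` or `"normalized"`.
#' @param gene_lengths optional named lengths (bp) for FPKM.
#' @return an `expression_table` object.
#' @export
expression_table <- function(values, design, mode = c("counts", "normalized"),
                             gene_lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!setequal(design$sample, colnames(values))) {
    stop("design samples do not match matrix columns")
  }
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  if (mode == "counts") {
    if (any(values < 0) || any(values != floor(values))) {
      stop("counts mode requires non-negative integer values")
    }
  }
  structure(list(values = values, design = design, mode = mode,
                 gene_lengths = gene_lengths),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$mode, "), tissues: ",
      paste(unique(x$design$tissue), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an expression table and design to TSV
#'
#' @param table an [expression_table].
#' @param counts_path,design_path output files.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(table, counts_path, design_path) {
  out <- data.frame(gene_id = rownames(table$values), table$values,
                    check.names = FALSE)
  write.table(out, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, design_path))
}

#' Read/write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so all tree
#' I/O flows through one place.
#'
#' @param path Newick file.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
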