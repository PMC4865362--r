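#' Read an allc-style per-cytosine call table
#'
#' The on-disk format is a 6-column tab-separated table
#' (`chrom  pos  strand  context  protected  total`), one row per reference
#' cytosine, positions 0-based. A header line is expected by default.
#'
#' @param path file to read.
#' @param source_kind see [call_table()].
#' @param sample_id sample label; defaults to the file name without extension.
#' @param header does the file carry a header line?
#' @return A [call_table()], sorted and validated. Rows violating
#'   `protected <= total` (or otherwise malformed) are reported with their
#'   file line numbers.
#' @export
read_calls <- function(path, source_kind = c("genome", "lambda_5mC", "pUC19_5hmC"),
                       sample_id = NULL, header = TRUE) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  cols <- c("chrom", "pos", "strand", "context", "protected", "total")
  df <- tryCatch(
    suppressWarnings(
    read.delim(path, header = header, sep = "\t",
               colClasses = c("character", "integer", "character",
                              "character", "integer", "integer"),
               col.names = cols, check.names = FALSE,
               stringsAsFactors = FALSE, quote = "")),
    error = function(e) stop_validation("malformed call table '", path, "': ",
                                        conditionMessage(e)))
  if (ncol(df) != 6L)
    stop_validation("call table '", path, "' must have 6 columns, found ", ncol(df))
  line0 <- if (header) 1L else 0L           # file line of row i is i + line0
  report <- function(rows, what) {
    stop_validation(what, " in '", path, "' at line(s) ",
                    paste(head(rows + line0, 5L), collapse = ", "))
  }
  bad <- which(is.na(df$pos) | is.na(df$protected) | is.na(df$total))
  if (length(bad)) report(bad, "non-integer count or position")
  bad <- which(df$protected > df$total)
  if (length(bad)) report(bad, "protected > total")
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad)) report(bad, "invalid strand")
  bad <- which(!(df$context %in% c("CG", "CHG", "CHH")))
  if (length(bad)) report(bad, "invalid context")
  call_table(df, sample_id = sample_id, source_kind = source_kind)
}

#' Write a call table to an allc-style TSV
#'
#' Inverse of [read_calls()]: `read_calls(write_calls(x, f))` reproduces `x`
#' field for field.
#'
#' @param table a [call_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(table, path) {
  if (!inherits(table, "call_table")) stop_validation("'table' must be a call_table")
  tryCatch(
    write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  invisible(path)
}

#' Read gene models from BED12 or GFF3
#'
#' Coordinates are normalised to the package-wide 0-based half-open
#' convention (BED is native; GFF3 starts are decremented on read). The
#' exonic length is the summed length of the exon blocks (BED12) or `exon`
#' features whose `Parent` is the gene (GFF3); a gene without exon features
#' gets its full span. The TSS is `start` for `+` strand genes and `end - 1`
#' for `-` strand genes.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame of class `"gene_models"` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `exonic_length`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3"
              else stop_validation("cannot infer annotation format from '", path, "'")
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) stop_validation("BED records must carry a name")
    blocks <- gr$blocks
    if (is.null(blocks)) {
      exlen <- GenomicRanges::width(gr)
    } else {
      exlen <- vapply(seq_along(gr), function(i) {
        b <- blocks[[i]]
        if (sum(IRanges::width(IRanges::reduce(b))) != sum(IRanges::width(b)))
          stop_validation("overlapping exon blocks in gene '", ids[i], "'")
        sum(IRanges::width(b))
      }, integer(1))
    }
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      exonic_length = as.integer(exlen),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    if (!length(genes)) stop_validation("no 'gene' features in '", path, "'")
    ids <- genes$ID
    if (is.null(ids) || anyNA(ids)) stop_validation("gene features must carry an ID")
    exons <- gr[type == "exon"]
    parent <- if (length(exons)) vapply(exons$Parent, function(p) p[1L], "") else character()
    exlen <- setNames(as.integer(GenomicRanges::width(genes)), ids)
    if (length(exons)) {
      for (id in intersect(unique(parent), ids)) {
        e <- IRanges::ranges(exons[parent == id])
        if (sum(IRanges::width(IRanges::reduce(e))) != sum(IRanges::width(e)))
          stop_validation("overlapping exon blocks in gene '", id, "'")
        exlen[id] <- sum(IRanges::width(e))
      }
    }
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(genes)),
                      strand = as.character(GenomicRanges::strand(genes)),
                      start = GenomicRanges::start(genes) - 1L,
                      end = GenomicRanges::end(genes),
                      exonic_length = exlen,
                      stringsAsFactors = FALSE)
  }
  gene_models(out)
}

#' Construct / validate a gene-model table
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open) and `exonic_length`.
#' @return the validated data.frame with class `"gene_models"`.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exonic_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("gene models missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$gene_id))
    stop_validation("duplicate gene_id: ", df$gene_id[which(duplicated(df$gene_id))[1L]])
  if (any(!(df$strand %in% c("+", "-"))))
    stop_validation("unknown strand for gene '",
                    df$gene_id[which(!(df$strand %in% c("+", "-")))[1L]], "'")
  if (any(df$start >= df$end))
    stop_validation("start >= end for gene '", df$gene_id[which(df$start >= df$end)[1L]], "'")
  if (any(df$exonic_length < 1L))
    stop_validation("exonic_length < 1 for gene '",
                    df$gene_id[which(df$exonic_length < 1L)[1L]], "'")
  if (any(df$exonic_length > df$end - df$start))
    stop_validation("exonic_length exceeds gene span for gene '",
                    df$gene_id[which(df$exonic_length > df$end - df$start)[1L]], "'")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$exonic_length <- as.integer(df$exonic_length)
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to BED12 or GFF3
#'
#' The exonic length is realised as one block when it equals the gene span and
#' otherwise as two blocks anchored at the gene ends (BED12 requires blocks to
#' touch both ends), so that [read_gene_models()] recovers the table exactly.
#'
#' @param genes a [gene_models()] table.
#' @param path output file.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  genes <- gene_models(genes)
  span <- genes$end - genes$start
  ex <- genes$exonic_length
  partial <- ex < span
  if (any(partial & ex < 2L))
    stop_validation("exonic_length 1 with a larger span cannot be written as blocks (gene '",
                    genes$gene_id[which(partial & ex < 2L)[1L]], "')")
  b1 <- ifelse(partial, pmin(ex - 1L, pmax(1L, ex %/% 2L)), ex)
  b2 <- ex - b1                                # second block ends at gene end
  if (format == "bed") {
    lines <- ifelse(!partial,
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
              genes$chrom, genes$start, genes$end, genes$gene_id, genes$strand,
              genes$start, genes$end, ex),
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t2\t%d,%d,\t0,%d,",
              genes$chrom, genes$start, genes$end, genes$gene_id, genes$strand,
              genes$start, genes$end, b1, b2, span - b2))
    writeLines(lines, path)
  } else {
    out <- c("##gff-version 3")
    for (i in seq_len(nrow(genes))) {
      out <- c(out, sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            genes$chrom[i], genes$start[i] + 1L, genes$end[i],
                            genes$strand[i], genes$gene_id[i]))
      es <- if (partial[i]) c(genes$start[i], genes$end[i] - b2[i])
            else genes$start[i]
      ee <- if (partial[i]) c(genes$start[i] + b1[i], genes$end[i])
            else genes$end[i]
      out <- c(out, sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                            genes$chrom[i], es + 1L, ee, genes$strand[i],
                            genes$gene_id[i], seq_along(es), genes$gene_id[i]))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated, one `gene_id` column plus one or more numeric sample
#' columns. Values must be non-negative; genes with missing values are kept
#' but flagged with a message.
#'
#' @param path file to read.
#' @return data.frame with `gene_id` first, one column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "")
  if (!("gene_id" %in% names(df))) names(df)[1L] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  if (ncol(df) < 2L) stop_validation("expression table needs at least one sample column")
  if (anyDuplicated(df$gene_id))
    stop_validation("duplicate gene_id: ", df$gene_id[which(duplicated(df$gene_id))[1L]])
  for (col in setdiff(names(df), "gene_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.na(v) & v < 0))
      stop_validation("negative expression for gene '",
                      df$gene_id[which(!is.na(v) & v < 0)[1L]], "' in column '", col, "'")
    df[[col]] <- v
  }
  n_na <- sum(!stats::complete.cases(df[-1L]))
  if (n_na) message(n_na, " gene(s) have missing expression values")
  rownames(df) <- NULL
  df
}
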