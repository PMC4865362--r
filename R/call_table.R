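#' Per-cytosine TAB-seq call tables
#'
#' A call table is the atom of all quantification in this package: one row per
#' reference cytosine carrying the number of reads that reported C
#' (`protected`, the 5hmC signal in TAB-seq) and the number of reads covering
#' the site (`total`). Positions are 0-based; `context` is derived from the
#' reference sequence on the strand of the cytosine.
#'
#' @param calls data.frame with columns `chrom` (character), `pos`
#'   (non-negative integer, 0-based), `strand` (`"+"` or `"-"`), `context`
#'   (one of `"CG"`, `"CHG"`, `"CHH"`), `protected` and `total`
#'   (non-negative integers with `protected <= total`).
#' @param sample_id label for the sample the calls came from.
#' @param source_kind what was sequenced: `"genome"` for the nuclear sample,
#'   `"lambda_5mC"` for the fully methylated lambda spike-in, `"pUC19_5hmC"`
#'   for the fully hydroxymethylated pUC19 spike-in.
#'
#' @return A data.frame of class `"call_table"`, sorted by
#'   `(chrom, pos, strand)`, with attributes `sample_id` and `source_kind`.
#'   Duplicate `(chrom, pos, strand)` rows are an error, never merged.
#' @examples
#' ct <- call_table(data.frame(
#'   chrom = "chr1", pos = c(10L, 14L), strand = "+",
#'   context = "CG", protected = c(1L, 0L), total = c(4L, 2L)))
#' ct
#' @export
call_table <- function(calls, sample_id = "sample",
                       source_kind = c("genome", "lambda_5mC", "pUC19_5hmC")) {
  source_kind <- match.arg(source_kind)
  need <- c("chrom", "pos", "strand", "context", "protected", "total")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop_validation("call table is missing column(s): ", paste(miss, collapse = ", "))
  calls <- as.data.frame(calls)[need]
  calls$chrom <- as.character(calls$chrom)
  calls$strand <- as.character(calls$strand)
  calls$context <- as.character(calls$context)
  for (col in c("pos", "protected", "total")) {
    v <- calls[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v)) || any(v < 0))
      stop_validation("column '", col, "' must contain non-negative integers")
    calls[[col]] <- as.integer(v)
  }
  bad <- which(!(calls$strand %in% c("+", "-")))
  if (length(bad))
    stop_validation("invalid strand at row(s) ", paste(head(bad, 5L), collapse = ", "))
  bad <- which(!(calls$context %in% c("CG", "CHG", "CHH")))
  if (length(bad))
    stop_validation("invalid context at row(s) ", paste(head(bad, 5L), collapse = ", "))
  bad <- which(calls$protected > calls$total)
  if (length(bad))
    stop_validation("protected > total at row(s) ", paste(head(bad, 5L), collapse = ", "))
  ord <- order(calls$chrom, calls$pos, calls$strand, method = "radix")
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key))
    stop_validation("duplicate (chrom, pos, strand) entries, e.g. ",
                    key[which(duplicated(key))[1L]])
  structure(calls,
            sample_id = sample_id,
            source_kind = source_kind,
            class = c("call_table", "data.frame"))
}

#' @export
print.call_table <- function(x, ...) {
  cat(sprintf("<call_table> sample '%s' (%s): %d sites, %s read observations\n",
              attr(x, "sample_id"), attr(x, "source_kind"),
              nrow(x), format(sum(as.numeric(x$total)), big.mark = ",")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

sample_id <- function(x) attr(x, "sample_id")
source_kind <- function(x) attr(x, "source_kind")

# Subset a call table while keeping class/attributes.
filter_calls <- function(x, keep) {
  y <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(y) <- NULL
  structure(y, sample_id = attr(x, "sample_id"),
            source_kind = attr(x, "source_kind"),
            class = c("call_table", "data.frame"))
}
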