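#' Exon-length-normalised expression scores
#'
#' RNA-seq read counts scale with the exonic length of a gene, so the
#' per-gene expression averaged over samples is divided by the gene's total
#' exonic length before ranking.
#'
#' @param expr expression table as returned by [read_expression()]
#'   (`gene_id` plus one or more numeric sample columns).
#' @param genes a [gene_models()] table supplying `exonic_length`. Genes in
#'   `expr` missing from the annotation are dropped with a message.
#' @return data.frame with columns `gene_id` and `score`
#'   (mean expression / exonic length).
#' @export
normalize_expression <- function(expr, genes) {
  if (!("gene_id" %in% names(expr)) || ncol(expr) < 2L)
    stop_validation("'expr' must have a gene_id column plus sample columns")
  idx <- match(expr$gene_id, genes$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped) message(dropped, " gene(s) not in the annotation were dropped")
  keep <- !is.na(idx)
  expr <- expr[keep, , drop = FALSE]
  exlen <- genes$exonic_length[idx[keep]]
  if (any(exlen <= 0))
    stop_validation("exonic_length must be positive (gene '",
                    expr$gene_id[which(exlen <= 0)[1L]], "')")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  data.frame(gene_id = expr$gene_id,
             score = rowMeans(m, na.rm = TRUE) / exlen,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic split of n genes into 5 quintiles: base size floor(n/5),
# the (n mod 5) lowest quintiles receive one extra gene.
quintile_sizes <- function(n) {
  as.integer(n %/% 5L + (seq_len(5L) <= n %% 5L))
}

#' Partition genes into expression quintiles
#'
#' Genes are sorted ascending by `(score, gene_id)` (ties broken
#' lexicographically in the C locale for reproducibility) and split into five
#' classes whose sizes differ by at most one; when `n` is not divisible by 5
#' the extra genes go to the lowest quintiles. Quintile 1 holds the lowest
#' scores, quintile 5 the highest.
#'
#' @param scores data.frame with `gene_id` and `score` columns (as from
#'   [normalize_expression()]), or a named numeric vector.
#' @return data.frame of class `"quintile_assignment"` with columns
#'   `gene_id`, `score`, `quintile`, ordered by `(score, gene_id)`; attribute
#'   `sizes` holds the five class sizes.
#' @examples
#' assign_quintiles(setNames(c(5, 1, 3, 2, 4), paste0("g", 1:5)))
#' @export
assign_quintiles <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- data.frame(gene_id = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% names(scores)))
    stop_validation("'scores' needs gene_id and score columns")
  n <- nrow(scores)
  if (n < 5L) stop_validation("need at least 5 genes to form quintiles, got ", n)
  if (anyDuplicated(scores$gene_id))
    stop_validation("duplicate gene_id in scores")
  ord <- order(scores$score, scores$gene_id, method = "radix")
  out <- data.frame(gene_id = scores$gene_id[ord],
                    score = scores$score[ord],
                    quintile = rep.int(1:5, quintile_sizes(n)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, sizes = quintile_sizes(n),
            class = c("quintile_assignment", "data.frame"))
}

#' @export
print.quintile_assignment <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat(sprintf("<quintile_assignment> %d genes; sizes (1=lowest): %s\n",
              nrow(x), paste(sz, collapse = ", ")))
  invisible(x)
}

#' Genes belonging to one quintile
#'
#' @param assignment a [assign_quintiles()] result.
#' @param q quintile in 1..5 (1 = lowest expression).
#' @return character vector of gene ids.
#' @export
quintile_genes <- function(assignment, q) {
  if (!q %in% 1:5) stop_validation("'q' must be in 1..5")
  assignment$gene_id[assignment$quintile == q]
}

#' Write quintile gene lists
#'
#' One gene-list TSV per quintile (`quintile1.tsv` .. `quintile5.tsv`) plus a
#' combined `quintile_assignment.tsv` (gene_id, score, quintile).
#'
#' @param assignment a [assign_quintiles()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_quintiles <- function(assignment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (q in 1:5)
    writeLines(quintile_genes(assignment, q), file.path(dir, sprintf("quintile%d.tsv", q)))
  write.table(as.data.frame(assignment), file.path(dir, "quintile_assignment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
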