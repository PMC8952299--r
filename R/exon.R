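# Per-exon read-depth bias screening. A transcript variant that drops a run
# of exons (ARV7-style: AR lacking exons 5-7) shows depleted coverage over
# those exons relative to the rest of the gene body.

#' Read-depth bias score over a set of query exons
#'
#' Computes the ratio of mean read depth over `query_exons` to mean depth over
#' `reference_exons`. A uniform coverage profile scores 1; a score below
#' `threshold` raises a flag indicating possible expression of a transcript
#' isoform lacking the query exons.
#'
#' @param depths named numeric vector of mean depth per exon (names are exon
#'   ids, e.g. `E1`..`E8`, ordered 5' to 3'), or a matrix exons x samples for
#'   per-sample scoring.
#' @param query_exons,reference_exons non-empty, disjoint character vectors of
#'   exon ids present in `depths`.
#' @param threshold flag threshold on the score (default 0.2).
#' @return For a vector input, a list with `score`, `flag`, `threshold`, and
#'   `undefined` (TRUE when the reference mean is zero, in which case `score`
#'   is `NA` and no flag is raised). For a matrix, a data.frame with one row
#'   per sample.
#' @examples
#' d <- setNames(c(100, 100, 100, 100, 0, 0, 0, 100), paste0("E", 1:8))
#' exon_bias_score(d, paste0("E", 5:7), paste0("E", 1:4))  # score 0, flagged
#' @export
exon_bias_score <- function(depths, query_exons, reference_exons,
                            threshold = 0.2) {
  if (length(query_exons) == 0L || length(reference_exons) == 0L)
    stop("query and reference exon lists must be non-empty")
  if (length(intersect(query_exons, reference_exons)) > 0L)
    stop("query and reference exon lists must be disjoint")
  if (is.matrix(depths)) {
    res <- lapply(seq_len(ncol(depths)), function(j)
      exon_bias_score(depths[, j], query_exons, reference_exons, threshold))
    return(data.frame(
      sample = colnames(depths) %||% as.character(seq_len(ncol(depths))),
      score = vapply(res, `[[`, numeric(1L), "score"),
      flag = vapply(res, `[[`, logical(1L), "flag"),
      undefined = vapply(res, `[[`, logical(1L), "undefined")))
  }
  miss <- setdiff(c(query_exons, reference_exons), names(depths))
  if (length(miss) > 0L)
    stop("exon id(s) not in profile: ", paste(miss, collapse = ", "))
  if (any(depths < 0)) stop("depths must be non-negative")
  qm <- mean(depths[query_exons])
  rm_ <- mean(depths[reference_exons])
  if (rm_ == 0)
    return(list(score = NA_real_, flag = FALSE, undefined = TRUE,
                threshold = threshold))
  s <- qm / rm_
  list(score = s, flag = s < threshold, undefined = FALSE,
       threshold = threshold)
}

#' Read per-exon depth profiles from TSV
#'
#' Expected columns: `gene_id`, `exon_id`, then one depth column per sample.
#' Exon order within a gene follows file order (5' to 3'). BED-style
#' coordinate columns (`chrom`, `start`, `end`), if present, are ignored:
#' only exon order and depth are used.
#'
#' @param path TSV file path.
#' @return Named list (by gene id) of depth matrices, exons x samples, with
#'   exon ids as rownames.
#' @export
read_exon_depth_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "exon_id")
  if (!all(need %in% names(df))) stop("TSV must have gene_id and exon_id columns")
  depth_cols <- setdiff(names(df), c(need, "chrom", "start", "end"))
  if (length(depth_cols) == 0L) stop("no depth columns found")
  split_df <- split(df, df$gene_id)
  lapply(split_df, function(g) {
    m <- as.matrix(g[, depth_cols, drop = FALSE])
    rownames(m) <- g$exon_id
    m
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
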