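# Expression containers: counts and RPKM matrices with sample metadata.

#' Treatment conditions of the organoid APDT design
#'
#' The four culture arms: androgen withdrawal (`NODHT`), androgen agonist
#' (`DHT`), agonist plus vehicle (`VEH`), and agonist plus enzalutamide
#' (`ENZA`). `NODHT` and `ENZA` are the two APDT (AR-antagonised) modalities;
#' `DHT` and `VEH` are their respective AR-agonist controls.
#'
#' @export
apdt_conditions <- function() c("NODHT", "DHT", "VEH", "ENZA")

.check_samples <- function(samples, ids) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "experiment", "condition")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L)
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(samples$condition %in% apdt_conditions()))
    stop("unknown condition label(s): ",
         paste(unique(setdiff(samples$condition, apdt_conditions())), collapse = ", "))
  if (!identical(as.character(samples$sample_id), as.character(ids)))
    stop("sample_id must match matrix column names, in order")
  invisible(samples)
}

#' RPKM expression matrix with sample metadata
#'
#' Container for a genes x samples matrix of RPKM values together with the
#' per-sample design (experiment 1/2, treatment condition, replicate).
#'
#' @param rpkm numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids); values must be non-negative.
#' @param samples data.frame with columns `sample_id`, `experiment`,
#'   `condition` (one of [apdt_conditions()]) and optionally `replicate`;
#'   `sample_id` must equal `colnames(rpkm)` in order.
#' @return An object of class `apdt_expression`: a list with elements `rpkm`
#'   and `samples`.
#' @examples
#' m <- matrix(1:8, 1, 8, dimnames = list("G1", paste0("s", 1:8)))
#' md <- data.frame(sample_id = paste0("s", 1:8),
#'                  experiment = rep(1:2, each = 4),
#'                  condition  = rep(apdt_conditions(), 2))
#' apdt_expression(m, md)
#' @export
apdt_expression <- function(rpkm, samples) {
  rpkm <- as.matrix(rpkm)
  if (!is.numeric(rpkm)) stop("rpkm must be numeric")
  if (is.null(rownames(rpkm)) || is.null(colnames(rpkm)))
    stop("rpkm must carry gene ids as rownames and sample ids as colnames")
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  samples <- as.data.frame(samples)
  .check_samples(samples, colnames(rpkm))
  structure(list(rpkm = rpkm, samples = samples), class = "apdt_expression")
}

#' @export
print.apdt_expression <- function(x, ...) {
  cat("APDT expression matrix:", nrow(x$rpkm), "genes x", ncol(x$rpkm), "samples\n")
  tab <- table(experiment = x$samples$experiment, condition = x$samples$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.apdt_expression <- function(x) dim(x$rpkm)

#' Count matrix with gene lengths and library sizes
#'
#' @param counts integer matrix of raw read counts, genes x samples.
#' @param gene_length numeric vector of transcript lengths in bases, named by
#'   gene id or in row order of `counts`.
#' @param total_mapped numeric vector of per-sample total mapped reads;
#'   defaults to the column sums of `counts`.
#' @param samples optional sample metadata data.frame (see
#'   [apdt_expression()]).
#' @return An object of class `apdt_counts`.
#' @export
apdt_counts <- function(counts, gene_length,
                        total_mapped = colSums(counts), samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_length))) {
    miss <- setdiff(rownames(counts), names(gene_length))
    if (length(miss) > 0L)
      stop("missing transcript length for gene(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    gene_length <- gene_length[rownames(counts)]
  } else if (length(gene_length) != nrow(counts)) {
    stop("gene_length must be named or match nrow(counts)")
  }
  if (any(!is.finite(gene_length) | gene_length <= 0))
    stop("transcript lengths must be positive")
  if (length(total_mapped) != ncol(counts))
    stop("total_mapped must have one entry per sample")
  if (any(total_mapped < colSums(counts)))
    stop("total mapped reads cannot be smaller than the column sum of counts")
  if (!is.null(samples)) .check_samples(as.data.frame(samples), colnames(counts))
  structure(list(counts = counts, gene_length = gene_length,
                 total_mapped = total_mapped, samples = samples),
            class = "apdt_counts")
}

#' Normalise raw counts to RPKM
#'
#' RPKM = reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (length_bases * total_mapped_reads)`. A zero count always
#' maps to zero RPKM, and jointly rescaling all counts and the library size
#' leaves RPKM unchanged.
#'
#' @param counts an [apdt_counts()] object.
#' @return An [apdt_expression()] object when `counts` carries sample
#'   metadata, otherwise a bare RPKM matrix.
#' @examples
#' cm <- apdt_counts(matrix(100, 1, 1, dimnames = list("G1", "s1")),
#'                   gene_length = c(G1 = 2000), total_mapped = 50e6)
#' compute_rpkm(cm)  # 1.0
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "apdt_counts"))
  rpkm <- counts$counts * 1e9 /
    outer(counts$gene_length, counts$total_mapped)
  dimnames(rpkm) <- dimnames(counts$counts)
  if (!is.null(counts$samples)) apdt_expression(rpkm, counts$samples) else rpkm
}

#' Set aside genes with no mapped reads
#'
#' Removes genes whose value is zero in every sample; a gene with signal in
#' any single sample is retained. Idempotent. The number of retained genes is
#' reported via `message()` and stored in the `n_retained` attribute.
#'
#' @param expr an [apdt_expression()] object or a bare numeric matrix.
#' @return Object of the same type with all-zero genes removed.
#' @export
filter_expressed <- function(expr) {
  m <- if (inherits(expr, "apdt_expression")) expr$rpkm else as.matrix(expr)
  keep <- rowSums(m != 0) > 0L
  message(sum(keep), " of ", nrow(m), " genes retained after expression filter")
  out <- if (inherits(expr, "apdt_expression"))
    apdt_expression(m[keep, , drop = FALSE], expr$samples)
  else m[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Read / write an expression matrix as TSV
#'
#' The TSV layout is genes in rows and samples in columns, with a `gene_id`
#' header field followed by sample ids of the form `E<experiment>_<condition>`
#' or `E<experiment>_<condition>_<replicate>`, from which sample metadata is
#' reconstructed.
#'
#' @param path file path.
#' @return [read_expression_tsv()] returns an [apdt_expression()] object.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  apdt_expression(m, parse_sample_ids(colnames(m)))
}

#' @rdname read_expression_tsv
#' @param expr an [apdt_expression()] object.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "apdt_expression"))
  df <- data.frame(gene_id = rownames(expr$rpkm), expr$rpkm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) < 2L || !grepl("^E[0-9]+$", p[1L]) ||
      !p[2L] %in% apdt_conditions(), logical(1L))
  if (any(bad))
    stop("cannot parse sample id(s): ", paste(ids[bad], collapse = ", "))
  data.frame(
    sample_id = ids,
    experiment = as.integer(sub("^E", "", vapply(parts, `[`, "", 1L))),
    condition = vapply(parts, `[`, "", 2L),
    replicate = vapply(parts, function(p)
      if (length(p) >= 3L) as.integer(p[3L]) else 1L, integer(1L)),
    stringsAsFactors = FALSE)
}
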