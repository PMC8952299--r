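# Query-based APDT response signature. The procedure accommodates
# inter-organoid variability without replicate-based test statistics:
# (1) per-experiment log2 fold changes between each APDT arm and its
#     AR-agonist control (NODHT vs DHT, ENZA vs VEH);
# (2) a concordance filter keeping genes that respond in the same direction,
#     above a magnitude threshold, in both experiments and both modalities;
# (3) inverse-variability ranking combined with fold-change ranking into a
#     global rank product;
# (4) classification into four classes by direction and control-arm
#     expression stratum (high/low RPKM).

#' Per-experiment APDT-vs-control log2 fold changes
#'
#' For every gene, computes `log2((NODHT + c) / (DHT + c))` and
#' `log2((ENZA + c) / (VEH + c))` within each experiment, where `c` is a
#' pseudocount in RPKM units that bounds fold changes at zero expression.
#' With more than one replicate per condition, condition means are contrasted.
#'
#' @param expr an [apdt_expression()] object containing all four conditions
#'   in both experiments.
#' @param pseudocount RPKM pseudocount `c` (default 0.5).
#' @return Numeric matrix, genes x 4, columns `E1_NODHT_vs_DHT`,
#'   `E1_ENZA_vs_VEH`, `E2_NODHT_vs_DHT`, `E2_ENZA_vs_VEH`; the pseudocount
#'   is stored as an attribute.
#' @export
compute_contrasts <- function(expr, pseudocount = 0.5) {
  stopifnot(inherits(expr, "apdt_expression"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  smp <- expr$samples
  cond_mean <- function(e, cond) {
    j <- which(smp$experiment == e & smp$condition == cond)
    if (length(j) == 0L)
      stop("missing condition ", cond, " in experiment ", e)
    rowMeans(expr$rpkm[, j, drop = FALSE])
  }
  cols <- list(
    E1_NODHT_vs_DHT = log2((cond_mean(1, "NODHT") + pseudocount) /
                           (cond_mean(1, "DHT") + pseudocount)),
    E1_ENZA_vs_VEH  = log2((cond_mean(1, "ENZA") + pseudocount) /
                           (cond_mean(1, "VEH") + pseudocount)),
    E2_NODHT_vs_DHT = log2((cond_mean(2, "NODHT") + pseudocount) /
                           (cond_mean(2, "DHT") + pseudocount)),
    E2_ENZA_vs_VEH  = log2((cond_mean(2, "ENZA") + pseudocount) /
                           (cond_mean(2, "VEH") + pseudocount)))
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(expr$rpkm)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Concordance filter across experiments and APDT modalities
#'
#' Retains genes whose four contrast values (two experiments x two APDT
#' modalities) share one sign and each reach `min_abs_log2fc` in magnitude.
#' A gene with any zero contrast is excluded (zero carries no sign). Raising
#' the threshold can only shrink the retained set.
#'
#' @param contrasts matrix from [compute_contrasts()].
#' @param min_abs_log2fc magnitude threshold (log2 units); a contrast equal
#'   to the threshold passes.
#' @return data.frame `gene_id`, `direction` (`"UP"`/`"DOWN"`),
#'   `mean_abs_log2fc`; threshold stored as an attribute.
#' @export
concordance_filter <- function(contrasts, min_abs_log2fc = 0.5) {
  if (min_abs_log2fc < 0) stop("min_abs_log2fc must be non-negative")
  sgn <- sign(contrasts)
  concordant <- (rowSums(sgn == 1L) == ncol(contrasts)) |
                (rowSums(sgn == -1L) == ncol(contrasts))
  big <- rowSums(abs(contrasts) >= min_abs_log2fc) == ncol(contrasts)
  keep <- which(concordant & big)
  data.frame(
    gene_id = rownames(contrasts)[keep],
    direction = ifelse(sgn[keep, 1L] > 0, "UP", "DOWN"),
    mean_abs_log2fc = rowMeans(abs(contrasts))[keep],
    stringsAsFactors = FALSE,
    row.names = NULL) -> out
  attr(out, "min_abs_log2fc") <- min_abs_log2fc
  out
}

#' Within-treatment variability score
#'
#' Genes are later ranked inversely by variability within same treatments.
#' Each arm groups biologically equivalent samples: by default the AR-agonist
#' pair (DHT, VEH) and the APDT pair (NODHT, ENZA), pooled over both
#' experiments — the design expects each pair to correlate. The score is the
#' mean coefficient of variation (population sd / mean — a descriptive
#' dispersion measure; with equal arm sizes the sd convention only rescales
#' scores and leaves the ranking unchanged) across arms; lower means more
#' consistent. An arm with zero mean has an undefined CV; such genes get an
#' infinite (worst) score and are flagged in the `flagged` attribute.
#'
#' @param expr an [apdt_expression()] object.
#' @param arms list of character vectors of condition labels defining the
#'   same-treatment groups.
#' @return Named numeric vector of scores (one per gene).
#' @examples
#' # arm values (10, 10) and (5, 15): CVs 0 and 0.5, score 0.25
#' @export
variability_score <- function(expr,
                              arms = list(control = c("DHT", "VEH"),
                                          apdt = c("NODHT", "ENZA"))) {
  stopifnot(inherits(expr, "apdt_expression"))
  cvs <- vapply(arms, function(conds) {
    j <- which(expr$samples$condition %in% conds)
    if (length(j) < 2L)
      stop("need >= 2 samples in arm {", paste(conds, collapse = ","), "}")
    m <- expr$rpkm[, j, drop = FALSE]
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))  # population sd: descriptive CV
    ifelse(mu == 0, NA_real_, s / mu)
  }, numeric(nrow(expr$rpkm)))
  if (nrow(expr$rpkm) == 1L) cvs <- matrix(cvs, nrow = 1L)
  score <- rowMeans(cvs)
  flagged <- !is.finite(score) | apply(cvs, 1L, function(v) any(is.na(v)))
  score[flagged] <- Inf
  names(score) <- rownames(expr$rpkm)
  attr(score, "flagged") <- names(score)[flagged]
  score
}

#' Global gene ranking by fold change and consistency
#'
#' Combines a rank by descending mean absolute log2 fold change with a rank
#' by ascending variability into a rank product; genes are ordered by
#' ascending rank product, ties broken lexicographically by gene id so the
#' ordering is deterministic.
#'
#' @param contrasts matrix from [compute_contrasts()].
#' @param variability named vector from [variability_score()], covering the
#'   same genes.
#' @return data.frame `gene_id`, `mean_abs_log2fc`, `variability`,
#'   `rank_product`, `rank` (1 = best), sorted by rank.
#' @export
global_rank <- function(contrasts, variability) {
  genes <- rownames(contrasts)
  if (!setequal(genes, names(variability)))
    stop("contrasts and variability must cover the same genes")
  v <- variability[genes]
  fc <- rowMeans(abs(contrasts))
  r_fc <- rank(-fc, ties.method = "average")
  r_var <- rank(v, ties.method = "average")
  rp <- r_fc * r_var
  ord <- order(rp, genes)
  data.frame(gene_id = genes[ord],
             mean_abs_log2fc = fc[ord],
             variability = unname(v[ord]),
             rank_product = rp[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split retained genes into four classes by direction and expression stratum
#'
#' Class is the cross of response direction (UP/DOWN) with the control-arm
#' expression stratum: HIGH when the mean RPKM over the AR-agonist control
#' conditions (DHT, VEH, all samples, both experiments) is at or above the
#' threshold, LOW otherwise (the boundary value goes HIGH).
#'
#' @param retained data.frame with `gene_id` and `direction` (from
#'   [concordance_filter()]).
#' @param expr an [apdt_expression()] object.
#' @param rpkm_threshold `"kmeans"` (default: deterministic 2-means on log2
#'   control RPKM of the retained genes, threshold at the midpoint of the
#'   cluster centres), `"median"` (median control RPKM of retained genes), or
#'   a fixed numeric RPKM value.
#' @param control_conditions conditions defining the control arm.
#' @return data.frame `gene_id`, `direction`, `class`, `mean_control_rpkm`;
#'   the resolved numeric threshold is kept in the `rpkm_threshold` attribute.
#' @export
classify_signature <- function(retained, expr, rpkm_threshold = "kmeans",
                               control_conditions = c("DHT", "VEH")) {
  stopifnot(inherits(expr, "apdt_expression"),
            all(c("gene_id", "direction") %in% names(retained)))
  j <- which(expr$samples$condition %in% control_conditions)
  ctrl <- rowMeans(expr$rpkm[retained$gene_id, j, drop = FALSE])
  thr <- resolve_rpkm_threshold(rpkm_threshold, ctrl)
  cls <- paste0(retained$direction, ifelse(ctrl >= thr, "_HIGH", "_LOW"))
  out <- data.frame(gene_id = retained$gene_id,
                    direction = retained$direction,
                    class = cls,
                    mean_control_rpkm = unname(ctrl),
                    stringsAsFactors = FALSE)
  attr(out, "rpkm_threshold") <- thr
  out
}

resolve_rpkm_threshold <- function(rpkm_threshold, ctrl) {
  if (is.numeric(rpkm_threshold)) return(rpkm_threshold)
  switch(match.arg(rpkm_threshold, c("kmeans", "median")),
    median = stats::median(ctrl),
    kmeans = {
      x <- log2(ctrl + 0.5)
      if (length(unique(x)) < 2L) return(stats::median(ctrl))
      # deterministic init at the quartiles; threshold = centre midpoint
      init <- matrix(stats::quantile(x, c(0.25, 0.75), names = FALSE))
      if (init[1L] == init[2L]) return(stats::median(ctrl))
      km <- stats::kmeans(x, centers = init)
      2^mean(km$centers) - 0.5
    })
}

#' Fit the query-based APDT response signature
#'
#' The central fitting function: filters unexpressed genes, computes the four
#' APDT-vs-control contrasts, applies the cross-experiment concordance
#' filter, scores within-treatment variability, derives the global rank
#' product, optionally truncates to the top `top_n` genes, and classifies the
#' signature into the DOWN_HIGH / DOWN_LOW / UP_HIGH / UP_LOW partition.
#'
#' @param expr an [apdt_expression()] object (both experiments, all four
#'   conditions).
#' @param min_abs_log2fc concordance magnitude threshold (log2 units).
#' @param pseudocount RPKM pseudocount for the fold changes.
#' @param rpkm_threshold high/low expression split rule; see
#'   [classify_signature()].
#' @param top_n optional cap on signature size after ranking.
#' @return An object of class `apdt_signature`: list with `table` (gene_id,
#'   direction, class, mean_control_rpkm, mean_abs_log2fc, variability,
#'   rank), `class_counts`, `contrasts`, `n_universe`, `params`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 500, seed = 3))
#' fit <- apdt_signature(sim$expr)
#' print(fit)
#' @export
apdt_signature <- function(expr, min_abs_log2fc = 0.5, pseudocount = 0.5,
                           rpkm_threshold = "kmeans", top_n = NULL) {
  expr <- suppressMessages(filter_expressed(expr))
  contrasts <- compute_contrasts(expr, pseudocount)
  retained <- concordance_filter(contrasts, min_abs_log2fc)
  variability <- variability_score(expr)
  ranking <- global_rank(contrasts[retained$gene_id, , drop = FALSE],
                         variability[retained$gene_id])
  if (!is.null(top_n) && nrow(ranking) > top_n)
    ranking <- ranking[seq_len(top_n), , drop = FALSE]
  retained <- retained[match(ranking$gene_id, retained$gene_id), ,
                       drop = FALSE]
  classified <- classify_signature(retained, expr, rpkm_threshold)
  tab <- data.frame(ranking["gene_id"],
                    direction = classified$direction,
                    class = classified$class,
                    mean_control_rpkm = classified$mean_control_rpkm,
                    mean_abs_log2fc = ranking$mean_abs_log2fc,
                    variability = ranking$variability,
                    rank = ranking$rank,
                    stringsAsFactors = FALSE)
  counts <- table(factor(tab$class, levels = c("DOWN_HIGH", "DOWN_LOW",
                                               "UP_HIGH", "UP_LOW")))
  structure(list(
    table = tab,
    class_counts = counts,
    contrasts = contrasts,
    n_universe = nrow(expr$rpkm),
    params = list(min_abs_log2fc = min_abs_log2fc,
                  pseudocount = pseudocount,
                  rpkm_threshold = attr(classified, "rpkm_threshold"),
                  rpkm_threshold_rule = rpkm_threshold,
                  top_n = top_n)),
    class = "apdt_signature")
}

#' @export
print.apdt_signature <- function(x, ...) {
  cat("APDT response signature:", nrow(x$table), "of", x$n_universe,
      "genes\n")
  print(x$class_counts)
  cat("min |log2FC|:", x$params$min_abs_log2fc,
      " pseudocount:", x$params$pseudocount,
      " high/low RPKM threshold:",
      signif(x$params$rpkm_threshold, 4), "\n")
  invisible(x)
}

#' @export
summary.apdt_signature <- function(object, n_top = 10L, ...) {
  cat("Query-based APDT response signature\n")
  cat("Universe:", object$n_universe, "expressed genes;",
      "signature:", nrow(object$table), "genes\n\n")
  print(object$class_counts)
  cat("\nTop-ranked genes:\n")
  print(utils::head(object$table, n_top), row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.apdt_signature <- function(x, ...) x$table

#' Signature gene ids, optionally by direction
#' @param fit an `apdt_signature` object.
#' @param direction `"ALL"`, `"UP"` or `"DOWN"`.
#' @export
signature_genes <- function(fit, direction = c("ALL", "UP", "DOWN")) {
  direction <- match.arg(direction)
  tab <- fit$table
  if (direction != "ALL") tab <- tab[tab$direction == direction, ]
  tab$gene_id
}

#' Write a fitted signature as TSV
#' @param fit an `apdt_signature` object.
#' @param path output path.
#' @export
write_signature_tsv <- function(fit, path) {
  utils::write.table(fit$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Heatmap of the signature as percentage of maximum RPKM
#'
#' Rows (genes, in hierarchical-cluster leaf order within each class) are
#' scaled to percent of their own maximum; columns are the eight samples.
#'
#' @param x an `apdt_signature` object.
#' @param expr the [apdt_expression()] the signature was fitted to.
#' @param ... passed to [graphics::image()].
#' @export
plot.apdt_signature <- function(x, expr, ...) {
  stopifnot(inherits(expr, "apdt_expression"))
  genes <- x$table$gene_id
  m <- percent_max_transform(expr$rpkm[genes, , drop = FALSE])
  ord <- unlist(lapply(split(genes, x$table$class), function(g) {
    if (length(g) < 2L) return(g)
    hierarchical_cluster(m[g, , drop = FALSE])$order
  }), use.names = FALSE)
  m <- m[ord, , drop = FALSE]
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, ...)
  graphics::axis(1L, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  invisible(m)
}

#' Scale each gene row to percentage of its maximum
#'
#' Every row is divided by its own maximum and multiplied by 100, so values
#' lie in \[0, 100\] and each row's maximum is exactly 100 (the display
#' transform used for signature heatmaps).
#'
#' @param mat numeric matrix with non-negative rows; an all-zero row is an
#'   error (such genes should have been filtered out).
#' @return Matrix of the same shape.
#' @export
percent_max_transform <- function(mat) {
  mat <- as.matrix(mat)
  mx <- apply(mat, 1L, max)
  if (any(mx <= 0))
    stop("row(s) with non-positive maximum: ",
         paste(utils::head(rownames(mat)[mx <= 0], 5L), collapse = ", "))
  sweep(mat, 1L, mx, `/`) * 100
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of gene rows with distance 1 - Pearson
#' correlation and average linkage; the leaf order returned by
#' [stats::hclust()] is deterministic for a given input. Rows with zero
#' variance have undefined correlation; they are assigned the maximal
#' distance (2) to every other row and reported in `flagged`.
#'
#' @param mat numeric matrix with >= 2 rows.
#' @return List with `order` (rownames in leaf order), `hclust` (the fitted
#'   tree), and `flagged` (zero-variance rownames).
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
  v <- apply(mat, 1L, stats::var)
  flagged <- rownames(mat)[v == 0]
  cors <- suppressWarnings(stats::cor(t(mat)))
  cors[!is.finite(cors)] <- -1  # max distance for undefined pairs
  diag(cors) <- 1
  d <- stats::as.dist(1 - cors)
  fit <- stats::hclust(d, method = "average")
  list(order = rownames(mat)[fit$order], hclust = fit, flagged = flagged)
}
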