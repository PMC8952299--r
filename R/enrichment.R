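# Merged-category over-representation analysis: fold-enrichment score
# E = (k/K) / (n/N) — the percent of differential genes inside a category
# relative to the percent of differential genes overall — with a Fisher 2x2
# exact test on the category-by-differential contingency table.

#' Merge overlapping gene sets into one functional category
#'
#' Overlapping gene sets sharing a functional theme (e.g. several cell-cycle
#' ontology and pathway sets) are unified into a single curated category:
#' the deduplicated union of their members, with the source set names kept
#' as provenance.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param name name of the merged category.
#' @return Object of class `merged_category`: list with `name`, `members`,
#'   `provenance`.
#' @examples
#' merge_gene_sets(list(A = c("a", "b"), B = c("b", "c")), "AB")$members
#' @export
merge_gene_sets <- function(sets, name) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  members <- unique(unlist(sets, use.names = FALSE))
  if (length(members) == 0L) stop("merged category has no members")
  structure(list(name = name, members = members,
                 provenance = names(sets) %||% rep(NA_character_,
                                                   length(sets))),
            class = "merged_category")
}

#' @export
print.merged_category <- function(x, ...) {
  cat("Merged category '", x$name, "': ", length(x$members), " genes from ",
      length(x$provenance), " source set(s)\n", sep = "")
  invisible(x)
}

#' Fisher's 2x2 exact test
#'
#' Exact test on the table `[[k, K-k], [n-k, (N-K)-(n-k)]]` (category row
#' first, differential column first). The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7 for floating-point ties). One-sided alternatives are
#' available via `alternative`.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to the \[1,1\] cell.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))  # 2/252
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L))) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  a <- m[1L, 1L]
  row1 <- a + m[1L, 2L]
  row2 <- m[2L, 1L] + m[2L, 2L]
  col1 <- a + m[2L, 1L]
  lo <- max(0L, col1 - row2)
  hi <- min(row1, col1)
  support <- lo:hi
  probs <- stats::dhyper(support, row1, row2, col1)
  p_obs <- probs[a - lo + 1L]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    stop("unknown alternative: ", alternative))
  min(p, 1)
}

#' Fold-enrichment score of a category against a signature
#'
#' `E = (k/K) / (n/N)` with `N` the universe size, `n` the differential
#' (signature) genes in the universe, `K` the category size after
#' intersection with the universe, and `k` the signature genes inside the
#' category. `E = 1` when the category composition matches the background;
#' `E` is undefined (`NA`) when `K = 0` or `n = 0`.
#'
#' @param category a `merged_category`, or a character vector of member ids.
#' @param signature_genes character vector of differential gene ids
#'   (intersected with the universe before counting).
#' @param universe character vector of evaluated gene ids.
#' @return One-row data.frame: `category`, `N`, `K`, `n`, `k`, `E`.
#' @export
enrichment_score <- function(category, signature_genes, universe) {
  if (inherits(category, "merged_category")) {
    nm <- category$name
    members <- category$members
  } else {
    nm <- deparse(substitute(category))
    members <- category
  }
  universe <- unique(universe)
  sig <- intersect(unique(signature_genes), universe)
  members <- intersect(unique(members), universe)
  N <- length(universe)
  n <- length(sig)
  K <- length(members)
  k <- length(intersect(members, sig))
  E <- if (K == 0L || n == 0L) NA_real_ else (k / K) / (n / N)
  data.frame(category = nm, N = N, K = K, n = n, k = k, E = E,
             stringsAsFactors = FALSE)
}

#' Enrichment of every category against a fitted signature
#'
#' Computes the fold-enrichment score and Fisher exact p for each category
#' against the combined signature, and additionally against its UP and DOWN
#' gene lists separately; the direction annotation names the stratum with
#' the smaller one-sided evidence. A Benjamini-Hochberg adjusted column
#' (`p_adj_bh`) is appended as supplementary output beyond the raw exact
#' p-values.
#'
#' @param categories named list of member-id vectors (e.g. [read_gmt()]
#'   output) and/or `merged_category` objects.
#' @param signature an `apdt_signature` fit, or a data.frame with `gene_id`
#'   and `direction` columns, or a plain character vector of gene ids (no
#'   direction annotation then).
#' @param universe character vector of evaluated gene ids (the
#'   expressed-gene universe the percentages are computed against).
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return data.frame, one row per category, sorted by ascending `p` then
#'   descending `E`: `category, N, K, n, k, E, p, E_up, p_up, E_down,
#'   p_down, direction, p_adj_bh`.
#' @export
enrich_all <- function(categories, signature, universe,
                       alternative = "two.sided") {
  if (inherits(signature, "apdt_signature")) {
    sig_tab <- signature$table[, c("gene_id", "direction")]
  } else if (is.data.frame(signature)) {
    sig_tab <- signature[, c("gene_id", "direction")]
  } else {
    sig_tab <- data.frame(gene_id = as.character(signature),
                          direction = NA_character_,
                          stringsAsFactors = FALSE)
  }
  universe <- unique(universe)
  have_dir <- !all(is.na(sig_tab$direction))
  fet <- function(sc) {
    tab <- matrix(c(sc$k, sc$K - sc$k,
                    sc$n - sc$k, (sc$N - sc$K) - (sc$n - sc$k)),
                  2L, 2L, byrow = TRUE)
    fisher_exact_2x2(tab, alternative)
  }
  one <- function(members, nm) {
    cat_obj <- if (inherits(members, "merged_category")) members else
      structure(list(name = nm, members = members), class = "merged_category")
    sc <- enrichment_score(cat_obj, sig_tab$gene_id, universe)
    sc$p <- fet(sc)
    if (have_dir) {
      for (d in c("UP", "DOWN")) {
        g <- sig_tab$gene_id[sig_tab$direction == d]
        sd_ <- enrichment_score(cat_obj, g, universe)
        sc[[paste0("E_", tolower(d))]] <- sd_$E
        sc[[paste0("p_", tolower(d))]] <- fet(sd_)
      }
      sc$direction <- if (isTRUE(sc$p_up <= sc$p_down)) "up" else "down"
    }
    sc
  }
  rows <- lapply(seq_along(categories), function(i)
    one(categories[[i]], names(categories)[i] %||% paste0("category_", i)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$E), , drop = FALSE]
  out$p_adj_bh <- stats::p.adjust(out$p, method = "BH")  # supplementary
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#' @param results data.frame from [enrich_all()].
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
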