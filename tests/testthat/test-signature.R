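# The query-based signature: contrasts, concordance, ranking, classes.

test_that("contrasts follow the pseudocount closed form", {
  e <- make_expr_conditions(nodht = 4, dht = 1, veh = 1, enza = 4)
  ctr <- compute_contrasts(e, pseudocount = 0.5)
  expect_equal(unname(ctr[1L, "E1_NODHT_vs_DHT"]), log2(4.5 / 1.5))
  flat <- make_expr_conditions(3, 3, 3, 3)
  expect_equal(unname(compute_contrasts(flat)[1L, ]), rep(0, 4L))
})

test_that("missing conditions are reported by experiment and name", {
  e <- make_expr(matrix(1, 1L, 8L))
  e$samples$condition[e$samples$condition == "ENZA" &
                      e$samples$experiment == 2L] <- "VEH"
  expect_error(compute_contrasts(e), "ENZA in experiment 2")
})

test_that("replicates are averaged before contrasting", {
  sim <- simulate_expression(sim_config(n_genes = 100L,
                                        within_treatment_cv = 0,
                                        planted_log2fc = 1,
                                        n_replicates_per_condition = 3L,
                                        seed = 5L))
  ctr <- compute_contrasts(sim$expr, pseudocount = 0)
  up <- sim$truth$gene_id[sim$truth$direction == "UP"]
  expect_equal(unname(ctr[up, ]), matrix(1, length(up), 4L))
})

test_that("concordance filter keeps same-sign genes above threshold", {
  ctr <- rbind(g1 = c(1.2, 0.8, 0.5, 0.9),    # concordant UP
               g2 = c(1.2, -0.8, 0.5, 0.9),   # sign conflict
               g3 = c(-1.2, -0.8, -0.5, -0.9),# concordant DOWN
               g4 = c(1.2, 0.8, 0, 0.9),      # zero has no sign
               g5 = c(1.2, 0.8, 0.3, 0.9))    # wording: all must reach it
  colnames(ctr) <- c("E1_NODHT_vs_DHT", "E1_ENZA_vs_VEH",
                     "E2_NODHT_vs_DHT", "E2_ENZA_vs_VEH")
  out <- concordance_filter(ctr, min_abs_log2fc = 0.5)
  expect_identical(out$gene_id, c("g1", "g3"))
  expect_identical(out$direction, c("UP", "DOWN"))
  # a contrast exactly at the threshold passes
  expect_true("g1" %in% concordance_filter(ctr, 0.5)$gene_id)
})

test_that("raising the threshold never enlarges the retained set", {
  sim <- simulate_expression(sim_config(n_genes = 1000L, seed = 17L))
  ctr <- compute_contrasts(sim$expr)
  prev <- concordance_filter(ctr, 0)$gene_id
  for (thr in c(0.25, 0.5, 1, 1.5, 2.5)) {
    cur <- concordance_filter(ctr, thr)$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("noise-free fixture is recovered exactly by the filter", {
  sim <- simulate_expression(sim_config(n_genes = 600L,
                                        within_treatment_cv = 0,
                                        planted_log2fc = 1, seed = 8L))
  ctr <- compute_contrasts(sim$expr, pseudocount = 0)
  out <- concordance_filter(ctr, min_abs_log2fc = 1)
  planted <- sim$truth[sim$truth$class != "NULL", ]
  expect_setequal(out$gene_id, planted$gene_id)
  expect_identical(out$direction[match(planted$gene_id, out$gene_id)],
                   planted$direction)
})

test_that("swapping APDT and control labels flips directions only", {
  sim <- simulate_expression(sim_config(n_genes = 500L, seed = 19L))
  ctr <- concordance_filter(compute_contrasts(sim$expr), 0.5)
  swapped <- sim$expr
  relabel <- c(NODHT = "DHT", DHT = "NODHT", ENZA = "VEH", VEH = "ENZA")
  swapped$samples$condition <- unname(relabel[swapped$samples$condition])
  ctr_sw <- concordance_filter(compute_contrasts(swapped), 0.5)
  expect_setequal(ctr$gene_id, ctr_sw$gene_id)
  m <- match(ctr$gene_id, ctr_sw$gene_id)
  expect_true(all(ctr$direction != ctr_sw$direction[m]))
})

test_that("variability score is a mean of per-arm CVs and scale-free", {
  # control arm (10, 10, 10, 10), APDT arm (5, 15, 5, 15):
  # population CVs 0 and 0.5 -> score 0.25
  e <- make_expr(matrix(c(5, 10, 10, 15, 15, 10, 10, 5), nrow = 1L))
  s <- variability_score(e)
  expect_equal(unname(s), 0.25, ignore_attr = TRUE)
  e10 <- make_expr(10 * e$rpkm)
  expect_equal(variability_score(e10), s, ignore_attr = TRUE)
  # identical values within every arm score zero
  flat <- make_expr_conditions(4, 9, 9, 4)
  expect_equal(unname(variability_score(flat)), 0, ignore_attr = TRUE)
  # zero-mean arm: worst score, flagged
  z <- make_expr(rbind(c(0, 1, 1, 0, 0, 1, 1, 0),
                       c(1, 1, 1, 1, 1, 1, 1, 1)))
  sz <- variability_score(z)
  expect_identical(unname(sz[1L]), Inf)
  expect_identical(attr(sz, "flagged"), "g001")
})

test_that("global ranking matches a brute-force rank product", {
  set.seed(33)
  n <- 20L
  ids <- sprintf("g%02d", 1:n)
  ctr <- matrix(stats::rnorm(n * 4L), n, dimnames = list(ids, NULL))
  ctr[3L, ] <- ctr[7L, ]  # force a tie
  vr <- stats::setNames(stats::runif(n), ids)
  vr[3L] <- vr[7L]
  res <- global_rank(ctr, vr)

  # brute force: counting ranks, average for ties, then rank product
  fc <- rowMeans(abs(ctr))
  bf_rank <- function(x, decreasing) {
    vapply(seq_along(x), function(i) {
      better <- if (decreasing) sum(x > x[i]) else sum(x < x[i])
      better + (sum(x == x[i]) + 1) / 2
    }, numeric(1L))
  }
  rp <- bf_rank(fc, TRUE) * bf_rank(unname(vr), FALSE)
  expect_identical(res$gene_id, ids[order(rp, ids)])
  expect_equal(res$rank_product,
               rp[match(res$gene_id, ids)], ignore_attr = TRUE)
  # the best gene on both criteria ranks first
  ctr2 <- rbind(best = c(5, 5, 5, 5), ctr)
  vr2 <- c(best = 0, vr)
  expect_identical(global_rank(ctr2, vr2)$gene_id[1L], "best")
  # tied genes sit adjacently, ordered by id
  i3 <- which(res$gene_id == "g03"); i7 <- which(res$gene_id == "g07")
  expect_identical(i7, i3 + 1L)
})

test_that("classification crosses direction with the expression stratum", {
  e <- make_expr(rbind(c(200, 50, 50, 200),   # UP, control mean 50
                       c(5, 10, 10, 5),       # DOWN, control mean 10
                       c(2, 1, 1, 2))[, c(1:4, 1:4)] )
  retained <- data.frame(gene_id = c("g001", "g002", "g003"),
                         direction = c("UP", "DOWN", "UP"))
  cls <- classify_signature(retained, e, rpkm_threshold = 10)
  expect_identical(cls$class, c("UP_HIGH", "DOWN_HIGH", "UP_LOW"))
  expect_equal(cls$mean_control_rpkm, c(50, 10, 1))
})

test_that("fitted signature partitions into four disjoint classes", {
  sim <- simulate_expression(sim_config(n_genes = 2000L, seed = 23L))
  fit <- suppressMessages(apdt_signature(sim$expr))
  expect_s3_class(fit, "apdt_signature")
  expect_equal(sum(fit$class_counts), nrow(fit$table))
  expect_false(anyDuplicated(fit$table$gene_id) > 0L)
  expect_setequal(unique(fit$table$class),
                  names(fit$class_counts)[fit$class_counts > 0L])
  expect_true(all(diff(fit$table$rank) == 1L))
  # direction consistent with every contrast of the gene
  sgn <- sign(fit$contrasts[fit$table$gene_id, , drop = FALSE])
  expect_true(all(sgn == ifelse(fit$table$direction == "UP", 1, -1)))
})

test_that("default fixture recovers planted classes at CV 0.2", {
  sim <- simulate_expression(sim_config(n_genes = 4000L, seed = 29L))
  fit <- suppressMessages(apdt_signature(sim$expr))
  truth <- sim$truth
  planted <- truth[truth$class != "NULL", ]
  m <- merge(fit$table, planted, by = "gene_id")
  expect_gt(nrow(m) / nrow(planted), 0.95)            # sensitivity
  expect_gt(mean(m$class.x == m$class.y), 0.95)       # class label recovery
})

test_that("percent-of-maximum transform scales rows to [0, 100]", {
  m <- rbind(a = c(2, 8, 4, 10), b = c(5, 5, 5, 5))
  pm <- percent_max_transform(m)
  expect_equal(unname(pm["a", ]), c(20, 80, 40, 100))
  expect_equal(unname(pm["b", ]), rep(100, 4L))
  expect_equal(percent_max_transform(pm), pm)  # idempotent
  expect_error(percent_max_transform(rbind(z = c(0, 0, 0))), "z")
})

test_that("hierarchical clustering uses correlation distance, average linkage", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
             c = c(4, 3, 2, 1), d = c(1, 3, 2, 5))
  hc <- hierarchical_cluster(m)
  # identical rows merge first at distance 0
  expect_equal(hc$hclust$height[1L], 0)
  expect_setequal(rownames(m)[-hc$hclust$merge[1L, ]], c("a", "b"))

  # brute-force average linkage on a 6-row fixture
  set.seed(41)
  m6 <- matrix(stats::rnorm(36), 6L, dimnames = list(letters[1:6], NULL))
  hc6 <- hierarchical_cluster(m6)
  d <- 1 - stats::cor(t(m6))
  clusters <- as.list(1:6)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1L]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1L])
    clusters[[best[3L]]] <- c(clusters[[best[3L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  expect_equal(hc6$hclust$height, heights)

  # zero-variance row is flagged and pushed to maximal distance
  mz <- rbind(m, z = c(2, 2, 2, 2))
  hz <- hierarchical_cluster(mz)
  expect_identical(hz$flagged, "z")
  expect_equal(max(hz$hclust$height), 2)
})
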