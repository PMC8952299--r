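# Synthetic expression data with planted ground truth. The generator mirrors
# the organoid study design: two independent experiments, four conditions
# (NODHT, DHT, VEH, ENZA), APDT-responsive genes planted concordantly in both
# experiments and both APDT modalities, in a high- and a low-expression
# stratum, under multiplicative lognormal noise.

#' Configuration for the synthetic expression generator
#'
#' Defaults reproduce the reference study design: 17,004 evaluated genes of
#' which 787 are planted as APDT-responsive — 312 down-regulated/high
#' expression, 206 down/low, 171 up/high and 98 up/low — with a single bulk
#' sample per condition per experiment.
#'
#' @param n_genes number of genes in the universe.
#' @param frac_planted_up,frac_planted_down proportions of genes planted as
#'   up-/down-regulated under APDT; their sum must be below 1.
#' @param planted_log2fc planted effect size in log2 units (> 0). Up-regulated
#'   genes have mean expression multiplied by `2^planted_log2fc` in the APDT
#'   arms (NODHT, ENZA) relative to the control arms (DHT, VEH); down-regulated
#'   genes are divided by the same factor.
#' @param high_low_split proportion of planted genes in the high-expression
#'   stratum; length 1 (shared) or 2 (`down`, `up` separately).
#' @param baseline_rpkm_high,baseline_rpkm_low control-arm mean expression
#'   (RPKM) of the two strata.
#' @param within_treatment_cv coefficient of variation of the multiplicative
#'   lognormal noise (>= 0; 0 gives a noise-free matrix equal to the means).
#' @param n_replicates_per_condition replicates per condition per experiment.
#' @param n_discordant number of planted genes whose effect direction is
#'   flipped in the enzalutamide modality (filter-negative controls; labelled
#'   `NULL` in the ground truth, marked `discordant`).
#' @param null_rpkm_meanlog,null_rpkm_sdlog lognormal parameters of the
#'   baseline expression of unplanted genes.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 17004L,
                       frac_planted_up = 269 / 17004,
                       frac_planted_down = 518 / 17004,
                       planted_log2fc = 2,
                       high_low_split = c(down = 312 / 518, up = 171 / 269),
                       baseline_rpkm_high = 100,
                       baseline_rpkm_low = 2,
                       within_treatment_cv = 0.2,
                       n_replicates_per_condition = 1L,
                       n_discordant = 0L,
                       null_rpkm_meanlog = log(8),
                       null_rpkm_sdlog = 1.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_planted_up = frac_planted_up,
              frac_planted_down = frac_planted_down,
              planted_log2fc = planted_log2fc,
              high_low_split = high_low_split,
              baseline_rpkm_high = baseline_rpkm_high,
              baseline_rpkm_low = baseline_rpkm_low,
              within_treatment_cv = within_treatment_cv,
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              n_discordant = as.integer(n_discordant),
              null_rpkm_meanlog = null_rpkm_meanlog,
              null_rpkm_sdlog = null_rpkm_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) stop("n_genes must be positive")
    if (frac_planted_up < 0 || frac_planted_down < 0 ||
        frac_planted_up + frac_planted_down >= 1)
      stop("planted fractions must be non-negative and sum to less than 1")
    if (planted_log2fc <= 0) stop("planted_log2fc must be positive")
    if (within_treatment_cv < 0) stop("within_treatment_cv must be >= 0")
    if (!length(high_low_split) %in% 1:2 ||
        any(high_low_split < 0 | high_low_split > 1))
      stop("high_low_split must be 1 or 2 proportions in [0, 1]")
    if (baseline_rpkm_high <= baseline_rpkm_low)
      stop("baseline_rpkm_high must exceed baseline_rpkm_low")
    if (n_replicates_per_condition < 1L) stop("need >= 1 replicate")
  })
  structure(cfg, class = "sim_config")
}

#' Planted class counts implied by a configuration
#'
#' @param config a [sim_config()].
#' @return Named integer vector with elements `DOWN_HIGH`, `DOWN_LOW`,
#'   `UP_HIGH`, `UP_LOW`.
#' @export
planted_counts <- function(config) {
  split <- config$high_low_split
  if (length(split) == 1L) split <- c(down = split, up = split)
  n_down <- round(config$frac_planted_down * config$n_genes)
  n_up <- round(config$frac_planted_up * config$n_genes)
  n_dh <- round(split[["down"]] * n_down)
  n_uh <- round(split[["up"]] * n_up)
  c(DOWN_HIGH = n_dh, DOWN_LOW = n_down - n_dh,
    UP_HIGH = n_uh, UP_LOW = n_up - n_uh)
}

#' Simulate an APDT expression experiment with planted ground truth
#'
#' Generates an RPKM matrix for 2 experiments x 4 conditions x replicates.
#' Planted up-regulated genes have their mean multiplied by
#' `2^planted_log2fc` in the APDT arms (NODHT, ENZA) of both experiments;
#' down-regulated genes are divided by it. Null genes share one mean across
#' all conditions. Values are the means perturbed by multiplicative lognormal
#' noise calibrated so that sd/mean equals `within_treatment_cv` (exact means
#' when the CV is 0). Identical config and seed reproduce the matrix exactly.
#'
#' @param config a [sim_config()].
#' @return List with elements `expr` (an [apdt_expression()]), `truth` (a
#'   data.frame with `gene_id`, `class` in DOWN_HIGH/DOWN_LOW/UP_HIGH/UP_LOW/
#'   NULL, `direction`, `stratum`, `baseline_rpkm`, `discordant`), and
#'   `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))

  counts <- planted_counts(config)
  n_planted <- sum(counts)
  if (n_planted + config$n_discordant > n)
    stop("planted plus discordant genes exceed the gene universe")
  perm <- sample.int(n)
  classes <- rep("NULL", n)
  idx <- 0L
  take <- function(k) {
    out <- perm[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  i_dh <- take(counts[["DOWN_HIGH"]]); classes[i_dh] <- "DOWN_HIGH"
  i_dl <- take(counts[["DOWN_LOW"]]);  classes[i_dl] <- "DOWN_LOW"
  i_uh <- take(counts[["UP_HIGH"]]);   classes[i_uh] <- "UP_HIGH"
  i_ul <- take(counts[["UP_LOW"]]);    classes[i_ul] <- "UP_LOW"
  i_disc <- take(config$n_discordant)
  discordant <- rep(FALSE, n); discordant[i_disc] <- TRUE

  direction <- rep("NULL", n)
  direction[classes %in% c("UP_HIGH", "UP_LOW")] <- "UP"
  direction[classes %in% c("DOWN_HIGH", "DOWN_LOW")] <- "DOWN"
  stratum <- rep(NA_character_, n)
  stratum[classes %in% c("UP_HIGH", "DOWN_HIGH")] <- "HIGH"
  stratum[classes %in% c("UP_LOW", "DOWN_LOW")] <- "LOW"
  # discordant controls sit in the high stratum with an UP-sized effect
  stratum[i_disc] <- "HIGH"

  baseline <- stats::rlnorm(n, config$null_rpkm_meanlog, config$null_rpkm_sdlog)
  baseline[stratum %in% "HIGH"] <- config$baseline_rpkm_high
  baseline[stratum %in% "LOW"] <- config$baseline_rpkm_low

  reps <- config$n_replicates_per_condition
  conds <- apdt_conditions()
  samples <- expand.grid(replicate = seq_len(reps), condition = conds,
                         experiment = 1:2, stringsAsFactors = FALSE)
  samples <- samples[, c("experiment", "condition", "replicate")]
  samples$sample_id <- if (reps == 1L)
    sprintf("E%d_%s", samples$experiment, samples$condition)
  else
    sprintf("E%d_%s_%d", samples$experiment, samples$condition,
            samples$replicate)
  samples <- samples[, c("sample_id", "experiment", "condition", "replicate")]

  # per-gene log2 effect applied in APDT arms, possibly modality-specific
  eff_nodht <- eff_enza <- rep(0, n)
  lfc <- config$planted_log2fc
  eff_nodht[direction == "UP"] <- lfc
  eff_nodht[direction == "DOWN"] <- -lfc
  eff_enza <- eff_nodht
  eff_nodht[i_disc] <- lfc
  eff_enza[i_disc] <- -lfc

  mu <- matrix(baseline, n, nrow(samples))
  apdt_arm <- samples$condition %in% c("NODHT", "ENZA")
  for (j in which(apdt_arm)) {
    eff <- if (samples$condition[j] == "NODHT") eff_nodht else eff_enza
    mu[, j] <- baseline * 2^eff
  }

  cv <- config$within_treatment_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog),
                    nrow(mu), ncol(mu))
    mat <- mu * noise
  } else {
    mat <- mu
  }
  dimnames(mat) <- list(gene_ids, samples$sample_id)

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      direction = direction,
                      stratum = ifelse(is.na(stratum), "NULL", stratum),
                      baseline_rpkm = baseline, discordant = discordant,
                      stringsAsFactors = FALSE)
  list(expr = apdt_expression(mat, samples), truth = truth, config = config)
}

#' Write a planted ground-truth table as TSV
#' @param truth the `truth` data.frame from [simulate_expression()].
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds `n_sets` gene sets over the simulated universe in which planted
#' (differential) genes appear at `enrichment_factor` times their background
#' rate: each member is a differential gene with probability
#' `min(enrichment_factor * n_diff / n_universe, 1)`, sampled without
#' replacement within a set. `enrichment_factor = 1` gives null sets whose
#' expected differential fraction equals the background fraction.
#'
#' @param truth ground-truth data.frame from [simulate_expression()] (or any
#'   data.frame with `gene_id` and `class` columns; `class != "NULL"` marks
#'   differential genes).
#' @param n_sets number of sets to generate.
#' @param enrichment_factor planted fold enrichment (>= 1).
#' @param size_range integer range of set sizes, sampled uniformly; spans the
#'   sizes of typical merged functional categories.
#' @param seed RNG seed.
#' @return Named list of character vectors (GMT-writable, see [write_gmt()]);
#'   the target in-set differential fraction is kept in the `target_fraction`
#'   attribute.
#' @export
simulate_gene_sets <- function(truth, n_sets = 50L, enrichment_factor = 1,
                               size_range = c(100L, 2000L), seed = 1L) {
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  set.seed(seed)
  universe <- truth$gene_id
  diff_genes <- truth$gene_id[truth$class != "NULL"]
  null_genes <- setdiff(universe, diff_genes)
  if (max(size_range) > length(universe))
    stop("set size range exceeds the gene universe")
  f_bg <- length(diff_genes) / length(universe)
  f <- min(enrichment_factor * f_bg, 1)
  sizes <- sample(seq.int(size_range[1L], size_range[2L]), n_sets,
                  replace = TRUE)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    m <- sizes[i]
    k_diff <- stats::rbinom(1L, m, f)
    k_diff <- min(k_diff, length(diff_genes))
    k_null <- min(m - k_diff, length(null_genes))
    sets[[i]] <- c(sample(diff_genes, k_diff), sample(null_genes, k_null))
  }
  names(sets) <- sprintf("SET%04d", seq_len(n_sets))
  attr(sets, "descriptions") <- stats::setNames(
    rep(sprintf("simulated, enrichment_factor=%g", enrichment_factor), n_sets),
    names(sets))
  attr(sets, "target_fraction") <- f
  sets
}
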