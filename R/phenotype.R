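# Fucci2BL cell-cycle state calling, dormancy and washout-reversibility
# statistics, and condition comparisons.

#' Call a cell-cycle state from Fucci2BL red/green intensities
#'
#' Red above threshold with green below calls G1/G0; green-only calls G2/M;
#' both above threshold is the yellow S state; neither is UNCLASSIFIED.
#' Decisions depend only on the threshold comparisons, so the call is
#' invariant to joint rescaling of intensities and thresholds.
#'
#' @param red,green non-negative intensity vectors (equal length).
#' @param red_threshold,green_threshold positive channel thresholds.
#' @return Character vector of states in `G1_G0`, `S`, `G2_M`,
#'   `UNCLASSIFIED`.
#' @examples
#' classify_state(500, 10, 100, 100)   # "G1_G0"
#' classify_state(500, 500, 100, 100)  # "S"
#' @export
classify_state <- function(red, green, red_threshold, green_threshold) {
  if (red_threshold <= 0 || green_threshold <= 0)
    stop("thresholds must be positive")
  if (any(red < 0) || any(green < 0)) stop("intensities must be non-negative")
  r <- red > red_threshold
  g <- green > green_threshold
  out <- rep("UNCLASSIFIED", length(red))
  out[r & !g] <- "G1_G0"
  out[!r & g] <- "G2_M"
  out[r & g] <- "S"
  out
}

#' Otsu threshold of an intensity distribution
#'
#' Histogram-based threshold maximising between-class variance; used as the
#' default per-channel cutoff separating the reporter's on and off states.
#'
#' @param x non-negative intensity vector.
#' @param n_breaks number of histogram bins.
#' @param log_scale threshold on log1p intensities (recommended for
#'   lognormal-like fluorescence), returning the cutoff on the original
#'   scale.
#' @return Numeric threshold.
#' @export
otsu_threshold <- function(x, n_breaks = 256L, log_scale = TRUE) {
  stopifnot(all(x >= 0))
  y <- if (log_scale) log1p(x) else x
  h <- graphics::hist(y, breaks = n_breaks, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  thr <- mids[which.max(sigma_b)]
  if (log_scale) expm1(thr) else thr
}

#' Add called states to a Fucci trace table
#'
#' @param traces data.frame with `red` and `green` columns (e.g. from
#'   [simulate_fucci()]).
#' @param red_threshold,green_threshold channel thresholds; `NULL` (default)
#'   derives each by [otsu_threshold()] over the full trace set.
#' @return `traces` with a `state` column; thresholds stored as attributes.
#' @export
classify_traces <- function(traces, red_threshold = NULL,
                            green_threshold = NULL) {
  if (is.null(red_threshold)) red_threshold <- otsu_threshold(traces$red)
  if (is.null(green_threshold)) green_threshold <- otsu_threshold(traces$green)
  traces$state <- classify_state(traces$red, traces$green,
                                 red_threshold, green_threshold)
  attr(traces, "red_threshold") <- red_threshold
  attr(traces, "green_threshold") <- green_threshold
  traces
}

#' Fraction of classified cells in the dormant G1/G0 state
#'
#' UNCLASSIFIED cells are excluded from the denominator and their count
#' reported. With `week = NULL` the fraction is computed for every week.
#'
#' @param traces data.frame with `week` and `state` columns (see
#'   [classify_traces()]).
#' @param week single week index, or `NULL` for all weeks.
#' @return data.frame `week`, `n_classified`, `n_unclassified`,
#'   `g0_fraction` (`NA` when no cell is classified that week).
#' @export
dormancy_fraction <- function(traces, week = NULL) {
  if (!"state" %in% names(traces))
    stop("traces carry no 'state' column; run classify_traces() first")
  if (!is.null(week)) traces <- traces[traces$week %in% week, , drop = FALSE]
  res <- lapply(split(traces, traces$week), function(d) {
    cls <- d$state != "UNCLASSIFIED"
    n_cls <- sum(cls)
    data.frame(week = d$week[1L],
               n_classified = n_cls,
               n_unclassified = sum(!cls),
               g0_fraction = if (n_cls == 0L) NA_real_
                             else sum(d$state == "G1_G0") / n_cls)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(is.na(out$g0_fraction)))
    warning("week(s) with zero classified cells: fraction undefined")
  out[order(out$week), , drop = FALSE]
}

#' Test whether drug washout reversed dormancy
#'
#' The washout week is the first non-ENZA week following at least one ENZA
#' week. Verdict is `REVERSED` when the G0 fraction immediately before
#' washout is at least `dormancy_level` and the first post-washout fraction
#' drops by at least `min_drop`; otherwise `NOT_REVERSED`.
#'
#' @param fractions numeric vector of per-week G0 fractions (or the
#'   data.frame from [dormancy_fraction()]).
#' @param schedule per-week treatment labels, same length.
#' @param dormancy_level minimum pre-washout G0 fraction (default 0.5).
#' @param min_drop minimum decrease after washout (default 0.2).
#' @return List: `verdict`, `pre`, `post`, `drop`, `washout_week`,
#'   `dormancy_level`, `min_drop`.
#' @export
reversibility_test <- function(fractions, schedule, dormancy_level = 0.5,
                               min_drop = 0.2) {
  if (is.data.frame(fractions)) {
    fractions <- fractions$g0_fraction[order(fractions$week)]
  }
  if (length(fractions) != length(schedule))
    stop("fractions and schedule must have the same length")
  is_enza <- schedule == "ENZA"
  washout <- which(!is_enza & c(FALSE, utils::head(is_enza, -1L)))
  if (length(washout) == 0L)
    stop("schedule contains no washout (ENZA followed by a non-ENZA week)")
  w <- washout[1L]
  pre <- fractions[w - 1L]
  post <- fractions[w]
  drop <- pre - post
  verdict <- if (pre >= dormancy_level && drop >= min_drop) "REVERSED"
             else "NOT_REVERSED"
  list(verdict = verdict, pre = pre, post = post, drop = drop,
       washout_week = w, dormancy_level = dormancy_level,
       min_drop = min_drop)
}

#' Normalise per-condition values to a reference condition
#'
#' @param values named numeric vector (names are condition labels).
#' @param reference reference condition (default `"NODHT"`, the androgen
#'   withdrawal arm); its value must be positive and maps to exactly 1.
#' @return Named vector of fold changes.
#' @export
fold_change_normalize <- function(values, reference = "NODHT") {
  if (!reference %in% names(values))
    stop("reference condition '", reference, "' not present")
  ref <- values[[reference]]
  if (ref == 0) stop("reference value is zero; fold change undefined")
  values / ref
}

#' Two-sample Student's t comparison of condition groups
#'
#' Equal-variance, two-sided Student's t-test by default (Welch available via
#' `var_equal = FALSE`). Significance stars follow the 0.05 / 0.01 / 0.0001
#' convention. Degenerate inputs with zero pooled variance are handled
#' explicitly: equal means give `t = 0, p = 1`; unequal means give `p = 0`
#' with a `degenerate` flag.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param var_equal pool variances (classic Student's t) when TRUE.
#' @return List: `t`, `df`, `p`, `stars`, `degenerate`.
#' @export
compare_conditions <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  stars = "", degenerate = TRUE))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2L, p = 0,
                stars = "***", degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  p <- fit$p.value
  stars <- if (p < 1e-4) "***" else if (p < 0.01) "**" else
           if (p < 0.05) "*" else ""
  list(t = unname(fit$statistic), df = unname(fit$parameter), p = p,
       stars = stars, degenerate = FALSE)
}
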