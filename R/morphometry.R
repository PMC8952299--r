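# Cyst/spheroid morphometry from labelled 2D masks. A cyst appears as a
# ring of epithelium around an empty lumen; its size statistic is the lumen
# diameter. A spheroid is a filled object; its statistic is the outlined
# area (and the equivalent-circle diameter for size filtering).

#' Measure objects in a labelled mask
#'
#' For every labelled object: area = pixel count x pixel size squared; an
#' object whose pixels fully enclose background (a hole) is typed as a cyst,
#' with lumen area equal to the hole area and lumen diameter the
#' equivalent-circle diameter `2 * sqrt(lumen_area / pi)`; an object without
#' a hole is a spheroid. Objects touching the image border are flagged and
#' meant to be excluded from statistics ([size_filter_and_count()] drops
#' them).
#'
#' @param mask integer label matrix (0 = background).
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param condition optional condition label attached to every record.
#' @return data.frame with one row per object: `object_id`, `type`,
#'   `area_um2`, `equiv_diameter_um`, `lumen_area_um2`, `lumen_diameter_um`
#'   (`NA` for spheroids), `touches_border`, `condition`. Empty mask gives
#'   zero rows.
#' @export
measure_objects <- function(mask, pixel_size_um = 1,
                            condition = NA_character_) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  mask <- as.matrix(mask)
  ids <- sort(setdiff(unique(as.integer(mask)), 0L))
  empty <- data.frame(object_id = integer(0), type = character(0),
                      area_um2 = numeric(0), equiv_diameter_um = numeric(0),
                      lumen_area_um2 = numeric(0),
                      lumen_diameter_um = numeric(0),
                      touches_border = logical(0), condition = character(0))
  if (length(ids) == 0L) return(empty)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- lapply(ids, function(id) {
    w <- which(mask == id, arr.ind = TRUE)
    touches <- any(w[, 1L] %in% c(1L, nr)) || any(w[, 2L] %in% c(1L, nc))
    # pad the bounding box by one background pixel so the flood fill can
    # travel around the object
    r0 <- max(1L, min(w[, 1L]) - 1L); r1 <- min(nr, max(w[, 1L]) + 1L)
    c0 <- max(1L, min(w[, 2L]) - 1L); c1 <- min(nc, max(w[, 2L]) + 1L)
    obj <- mask[r0:r1, c0:c1, drop = FALSE] == id
    holes <- sum(find_holes(obj))
    area <- nrow(w) * pixel_size_um^2
    lumen_area <- holes * pixel_size_um^2
    is_cyst <- holes > 0L
    data.frame(
      object_id = id,
      type = if (is_cyst) "cyst" else "spheroid",
      area_um2 = area,
      equiv_diameter_um = 2 * sqrt(area / pi),
      lumen_area_um2 = lumen_area,
      lumen_diameter_um = if (is_cyst) 2 * sqrt(lumen_area / pi)
                          else NA_real_,
      touches_border = touches,
      condition = condition,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Logical matrix of enclosed-background pixels: background not reachable
# from the matrix border through 4-connected background moves. Vectorised
# frontier expansion; matrices are per-object bounding boxes, so small.
find_holes <- function(obj) {
  bg <- !obj
  nr <- nrow(bg); nc <- ncol(bg)
  reach <- matrix(FALSE, nr, nc)
  reach[1L, ] <- bg[1L, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1L] <- reach[, 1L] | bg[, 1L]
  reach[, nc] <- reach[, nc] | bg[, nc]
  repeat {
    grown <- reach
    grown[-1L, ] <- grown[-1L, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1L, ]
    grown[, -1L] <- grown[, -1L] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1L]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  bg & !reach
}

#' Apply the 50-micron size filter and count objects per condition
#'
#' Spheroids are kept when their equivalent-circle diameter is at least
#' `min_size_um` (inclusive: "at least 50 um"); cysts when their lumen
#' diameter strictly exceeds it ("greater than 50 um"). Both comparison
#' rules are configurable. Border-touching objects are excluded first.
#'
#' @param records data.frame from [measure_objects()].
#' @param min_size_um size threshold in micrometres (default 50).
#' @param cyst_rule,spheroid_rule comparison operator as a string (`">"`,
#'   `">="`).
#' @return List with `counts` (data.frame `condition`, `type`, `n`) and
#'   `kept` (the filtered records).
#' @export
size_filter_and_count <- function(records, min_size_um = 50,
                                  cyst_rule = ">", spheroid_rule = ">=") {
  cyst_cmp <- match.fun(cyst_rule)
  sph_cmp <- match.fun(spheroid_rule)
  rec <- records[!records$touches_border, , drop = FALSE]
  keep <- ifelse(rec$type == "cyst",
                 cyst_cmp(rec$lumen_diameter_um, min_size_um),
                 sph_cmp(rec$equiv_diameter_um, min_size_um))
  kept <- rec[keep %in% TRUE, , drop = FALSE]
  counts <- as.data.frame(table(condition = kept$condition,
                                type = factor(kept$type,
                                              c("cyst", "spheroid"))),
                          responseName = "n", stringsAsFactors = FALSE)
  list(counts = counts, kept = kept)
}
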