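# Synthetic labelled masks of organoid cross-sections: hollow epithelial
# cysts rendered as annuli (known lumen radius) and cell-filled spheroids as
# discs (known area). Feeds the morphometry stage with analytic ground truth.

#' Simulate a labelled mask of cysts and spheroids
#'
#' Objects are placed uniformly at random without overlap (bounding-circle
#' test with `min_gap_px` clearance); each placement is retried up to
#' `max_retries` times before failing. A pixel belongs to a disc when its
#' centre lies within the radius.
#'
#' @param n_cysts,n_spheroids object counts.
#' @param cyst_lumen_radius_um,cyst_wall_um,spheroid_radius_um length-2
#'   ranges (micrometres) sampled uniformly for, respectively, cyst lumen
#'   radius, cyst wall thickness, and spheroid radius.
#' @param image_size_px `c(rows, cols)` of the label image.
#' @param pixel_size_um physical pixel size (> 0).
#' @param min_gap_px minimum clearance between object bounding circles.
#' @param max_retries placement retries per object before erroring.
#' @param condition optional condition label stored in the truth table.
#' @param seed RNG seed.
#' @return List with `mask` (integer matrix, 0 = background, k = object k)
#'   and `truth` (data.frame: `object_id`, `type`, `center_row`, `center_col`,
#'   `outer_radius_um`, `lumen_radius_um`, `true_area_um2`,
#'   `true_lumen_diameter_um`, `condition`).
#' @examples
#' m <- simulate_masks(n_cysts = 2, n_spheroids = 3, seed = 7)
#' table(m$truth$type)
#' @export
simulate_masks <- function(n_cysts = 5L, n_spheroids = 5L,
                           cyst_lumen_radius_um = c(20, 60),
                           cyst_wall_um = c(8, 15),
                           spheroid_radius_um = c(20, 60),
                           image_size_px = c(1024L, 1024L),
                           pixel_size_um = 1,
                           min_gap_px = 3L,
                           max_retries = 200L,
                           condition = NA_character_,
                           seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  set.seed(seed)
  nr <- image_size_px[1L]; nc <- image_size_px[2L]
  mask <- matrix(0L, nr, nc)
  n_obj <- n_cysts + n_spheroids
  placed <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  truth <- vector("list", n_obj)

  runif_range <- function(rg) stats::runif(1L, rg[1L], rg[2L])
  for (k in seq_len(n_obj)) {
    is_cyst <- k <= n_cysts
    if (is_cyst) {
      lumen_um <- runif_range(cyst_lumen_radius_um)
      outer_um <- lumen_um + runif_range(cyst_wall_um)
    } else {
      outer_um <- runif_range(spheroid_radius_um)
      lumen_um <- NA_real_
    }
    r_px <- outer_um / pixel_size_um
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cr <- stats::runif(1L, r_px + 2, nr - r_px - 1)
      cc <- stats::runif(1L, r_px + 2, nc - r_px - 1)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$row - cr)^2 + (placed$col - cc)^2) >
              placed$r + r_px + min_gap_px)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place object ", k, " after ", max_retries,
                  " retries; reduce object count or size")
    placed <- rbind(placed, data.frame(row = cr, col = cc, r = r_px))

    rows <- max(1L, floor(cr - r_px - 1)):min(nr, ceiling(cr + r_px + 1))
    cols <- max(1L, floor(cc - r_px - 1)):min(nc, ceiling(cc + r_px + 1))
    d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    inside <- d2 <= r_px^2
    if (is_cyst) inside <- inside & d2 > (lumen_um / pixel_size_um)^2
    sub <- mask[rows, cols]
    sub[inside] <- k
    mask[rows, cols] <- sub

    truth[[k]] <- data.frame(
      object_id = k,
      type = if (is_cyst) "cyst" else "spheroid",
      center_row = cr, center_col = cc,
      outer_radius_um = outer_um,
      lumen_radius_um = lumen_um,
      true_area_um2 = if (is_cyst) pi * (outer_um^2 - lumen_um^2)
                      else pi * outer_um^2,
      true_lumen_diameter_um = if (is_cyst) 2 * lumen_um else NA_real_,
      condition = condition,
      stringsAsFactors = FALSE)
  }
  list(mask = mask, truth = do.call(rbind, truth))
}

#' Write a label mask as a 16-bit-range PNG
#'
#' Object ids (0 = background) are split across the red (high byte) and
#' green (low byte) 8-bit channels, so up to 65535 labels round-trip
#' exactly.
#'
#' @param mask integer label matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored")
  img <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  img[, , 1L] <- (mask %/% 256L) / 255
  img[, , 2L] <- (mask %% 256L) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png()]
#' @param path PNG path.
#' @return Integer label matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || dim(img)[3L] < 2L)
    stop("not a label PNG written by write_mask_png()")
  hi <- round(img[, , 1L] * 255)
  lo <- round(img[, , 2L] * 255)
  matrix(as.integer(hi * 256L + lo), dim(img)[1L], dim(img)[2L])
}
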