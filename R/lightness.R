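# HSL colour lightness from photograph pixel samples.

#' HSL lightness of RGB pixels
#'
#' Lightness in the bi-hexcone HSL colour model:
#' `L = (max(R, G, B) + min(R, G, B)) / 2 / 255 * 100`, in percent.
#'
#' @param rgb an integer vector of length 3 `(R, G, B)` or an `n x 3`
#'   matrix of such triples, channels in `[0, 255]`.
#' @return numeric vector of lightness values in `[0, 100]`.
#' @examples
#' rgb_to_lightness(c(255, 255, 255))  # 100
#' rgb_to_lightness(c(255, 0, 0))      # 50
#' @export
rgb_to_lightness <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(m) != 3) stop("rgb must have three channels")
  if (anyNA(m) || any(m < 0 | m > 255)) stop("RGB channels must lie in [0, 255]")
  (apply(m, 1, max) + apply(m, 1, min)) / 2 / 255 * 100
}

#' Species colour lightness from a pixel sample
#'
#' Averages the HSL lightness of pixels sampled from a fruit-body
#' photograph. The sampling protocol expects nine pixels per species; a
#' different count is accepted with a warning.
#'
#' @param rgb an `n x 3` matrix of RGB triples (one row per sampled pixel).
#' @param n_expected expected number of pixels per sample (default 9).
#' @return a single lightness value in `[0, 100]`.
#' @export
species_lightness <- function(rgb, n_expected = 9) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3, byrow = TRUE)
  if (nrow(m) == 0) stop("empty pixel sample")
  if (nrow(m) != n_expected) {
    warning("pixel sample has ", nrow(m), " pixels, expected ", n_expected)
  }
  mean(rgb_to_lightness(m))
}

#' Extract per-species lightness from images and a pixel-coordinate file
#'
#' Batch form of the photograph protocol: pixel coordinates are recorded
#' in a sample file so a lightness extraction is reproducible. Images must
#' be 8-bit RGB (or greyscale) PNG files.
#'
#' @param pixels a data frame or CSV path with columns `species_id`,
#'   `image_file`, `row`, `col` (1-based pixel coordinates).
#' @param image_dir directory containing the image files.
#' @param n_expected expected pixels per species (default 9).
#' @return a `data.frame` with columns `species_id`, `lightness_pct`,
#'   `n_pixels`.
#' @export
extract_species_lightness <- function(pixels, image_dir = ".", n_expected = 9) {
  px <- if (is.character(pixels)) read.csv(pixels, stringsAsFactors = FALSE) else as.data.frame(pixels)
  need <- c("species_id", "image_file", "row", "col")
  miss <- setdiff(need, names(px))
  if (length(miss)) stop("pixel file lacks columns: ", paste(miss, collapse = ", "))
  imgs <- new.env(parent = emptyenv())
  read_img <- function(f) {
    if (!is.null(imgs[[f]])) return(imgs[[f]])
    path <- file.path(image_dir, f)
    if (!file.exists(path)) stop("image not found: ", path)
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
    imgs[[f]] <- a
    a
  }
  per_pixel <- function(i) {
    a <- read_img(px$image_file[i])
    r <- px$row[i]; cc <- px$col[i]
    if (r < 1 || r > dim(a)[1] || cc < 1 || cc > dim(a)[2]) {
      stop("pixel (", r, ", ", cc, ") outside image ", px$image_file[i])
    }
    ch <- a[r, cc, ]
    v <- round(ch[seq_len(min(3, length(ch)))] * 255)
    if (length(v) == 1) v <- rep(v, 3)  # greyscale image
    rgb_to_lightness(v)
  }
  light <- vapply(seq_len(nrow(px)), per_pixel, numeric(1))
  sp <- split(light, px$species_id)
  out <- data.frame(species_id = names(sp),
                    lightness_pct = vapply(sp, mean, numeric(1)),
                    n_pixels = vapply(sp, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  off <- out$n_pixels != n_expected
  if (any(off)) {
    warning("pixel count differs from ", n_expected, " for: ",
            paste(out$species_id[off], collapse = ", "))
  }
  out
}
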