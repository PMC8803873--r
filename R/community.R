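# Community matrix assembly, filtering and per-log community trait means.

#' Aggregate yearly fruit-body records into a presence/absence matrix
#'
#' Collapses long-format survey records (one row per year x log x species
#' occurrence) into a binary community matrix: a species is present on a
#' log if it was recorded in any retained survey year. By default the
#' first survey year is excluded (too few records for meaningful
#' community means). Species never observed in the retained years are
#' dropped with a message.
#'
#' @param records data frame with columns `year`, `log_id`, `species_id`.
#' @param exclude_years years to drop; default the earliest year present.
#' @param meta optional log metadata (see [generate_deadwood_metadata()]);
#'   when given, the matrix rows cover every sampled log (zero rows for
#'   logs without records) and unknown `log_id`s are an error.
#' @return binary integer matrix, rows = logs, columns = species.
#' @export
aggregate_years <- function(records, exclude_years = NULL, meta = NULL) {
  rec <- as.data.frame(records)
  need <- c("year", "log_id", "species_id")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (nrow(rec) == 0) stop("empty record set")
  if (is.null(exclude_years)) exclude_years <- min(rec$year)
  if (!is.null(meta)) {
    unknown <- setdiff(rec$log_id, meta$log_id)
    if (length(unknown)) stop("records reference unknown log_id: ",
                              paste(unknown, collapse = ", "))
    logs <- as.character(meta$log_id)
  } else {
    logs <- sort(unique(as.character(rec$log_id)))
  }
  species <- sort(unique(as.character(rec$species_id)))
  m <- matrix(0L, nrow = length(logs), ncol = length(species),
              dimnames = list(logs, species))
  keep <- !(rec$year %in% exclude_years)
  if (any(keep)) {
    m[cbind(as.character(rec$log_id[keep]), as.character(rec$species_id[keep]))] <- 1L
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " species with no occurrence in retained years")
    m <- m[, !empty, drop = FALSE]
  }
  m
}

#' Filter logs by minimum species richness
#'
#' Community trait means are only meaningful for logs carrying several
#' species; the default threshold is three species per log (one can be
#' used as a sensitivity setting). Columns are left untouched.
#'
#' @param m binary community matrix (logs x species).
#' @param k minimum row sum to retain (default 3).
#' @return the matrix restricted to rows with at least `k` occurrences.
#' @export
filter_min_richness <- function(m, k = 3) {
  stopifnot(k >= 1)
  m[rowSums(m) >= k, , drop = FALSE]
}

# Per-species transformed trait vectors + masks used by both the observed
# community means and the null-model statistic. Errors on non-positive
# size/lightness for species that actually occur (log10 undefined).
.trait_stat_inputs <- function(m, traits) {
  tr <- as.data.frame(traits)
  missing_sp <- setdiff(colnames(m), tr$species_id)
  if (length(missing_sp)) stop("trait table lacks species: ",
                               paste(missing_sp, collapse = ", "))
  tr <- tr[match(colnames(m), tr$species_id), ]
  occ <- colSums(m) > 0
  bad_size <- occ & !is.na(tr$size_mm) & tr$size_mm <= 0
  if (any(bad_size)) stop("non-positive fruit-body size (log10 undefined) for: ",
                          paste(tr$species_id[bad_size], collapse = ", "))
  bad_light <- occ & !is.na(tr$lightness_pct) & tr$lightness_pct <= 0
  if (any(bad_light)) stop("non-positive lightness (log10 undefined) for: ",
                           paste(tr$species_id[bad_light], collapse = ", "))
  size_mask <- as.numeric(!is.na(tr$size_mm))
  light_mask <- as.numeric(!is.na(tr$lightness_pct))
  tough_mask <- as.numeric(!is.na(tr$toughness))
  list(
    size_val = ifelse(size_mask == 1, log10(tr$size_mm), 0),
    size_mask = size_mask,
    light_val = ifelse(light_mask == 1, log10(tr$lightness_pct), 0),
    light_mask = light_mask,
    tough_val = as.numeric(!is.na(tr$toughness) & tr$toughness == "tough"),
    tough_mask = tough_mask,
    lineage = tr$lineage
  )
}

# Community trait statistics for one binary matrix given precomputed
# inputs: columns mean_log10_size, mean_log10_lightness, prop_tough.
.community_stats <- function(m, si) {
  sums <- m %*% cbind(si$size_val * si$size_mask, si$size_mask,
                      si$light_val * si$light_mask, si$light_mask,
                      si$tough_val * si$tough_mask, si$tough_mask)
  size <- ifelse(sums[, 2] > 0, sums[, 1] / sums[, 2], NA_real_)
  light <- ifelse(sums[, 4] > 0, sums[, 3] / sums[, 4], NA_real_)
  tough <- ifelse(sums[, 6] > 0, sums[, 5] / sums[, 6], NA_real_)
  cbind(mean_log10_size = size, mean_log10_lightness = light, prop_tough = tough)
}

#' Per-log community trait means
#'
#' Computes the three community responses for each log: the mean of the
#' log10-transformed mean fruit-body size over the species present, the
#' mean of the log10-transformed colour lightness, and the proportion of
#' tough-fleshed species (arcsine-square-root transformed for modelling).
#' Species missing a trait are excluded from that trait's mean only. With
#' a lineage scope the matrix is first restricted to that lineage's
#' species and re-filtered by the richness threshold.
#'
#' @param m binary community matrix (logs x species).
#' @param traits trait table as returned by [build_trait_table()].
#' @param lineage_scope `"all"`, `"Basidiomycota"` or `"Ascomycota"`.
#' @param min_richness minimum per-log richness within the scope (default 3).
#' @param toughness_transform `"asin_sqrt"` (the variance-stabilising
#'   `asin(sqrt(p))`, default) or `"asin"` (plain `asin(p)`).
#' @return a `data.frame` with columns `log_id`, `richness`,
#'   `mean_log10_size`, `mean_log10_lightness`, `prop_tough`,
#'   `prop_tough_asin`, `lineage_scope`.
#' @examples
#' m <- matrix(1L, 1, 2, dimnames = list("L1", c("a", "b")))
#' tr <- data.frame(species_id = c("a", "b"), lineage = "Basidiomycota",
#'                  size_mm = c(10, 1000), lightness_pct = c(10, 100),
#'                  toughness = c("tough", "soft"))
#' community_trait_means(m, tr, min_richness = 1)
#' @export
community_trait_means <- function(m, traits,
                                  lineage_scope = c("all", "Basidiomycota", "Ascomycota"),
                                  min_richness = 3,
                                  toughness_transform = c("asin_sqrt", "asin")) {
  lineage_scope <- match.arg(lineage_scope)
  toughness_transform <- match.arg(toughness_transform)
  tr <- as.data.frame(traits)
  if (lineage_scope != "all") {
    keep <- colnames(m) %in% tr$species_id[tr$lineage == lineage_scope]
    m <- m[, keep, drop = FALSE]
  }
  m <- filter_min_richness(m, min_richness)
  si <- .trait_stat_inputs(m, tr)
  st <- .community_stats(m, si)
  p <- st[, "prop_tough"]
  pt_asin <- if (toughness_transform == "asin_sqrt") asin(sqrt(p)) else asin(p)
  data.frame(log_id = rownames(m),
             richness = as.integer(rowSums(m)),
             mean_log10_size = st[, "mean_log10_size"],
             mean_log10_lightness = st[, "mean_log10_lightness"],
             prop_tough = p,
             prop_tough_asin = pt_asin,
             lineage_scope = lineage_scope,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Lateral surface area of a truncated cone
#'
#' Dead-wood amount per plot is characterised by log surface area, using
#' the frustum (truncated cone) formula with the two end diameters and the
#' log length: `pi * (r1 + r2) * sqrt(L^2 + (r1 - r2)^2)`. End caps are
#' excluded by default.
#'
#' @param d1_m,d2_m end diameters in metres.
#' @param length_m log length in metres.
#' @param ends if `TRUE`, add the two circular end caps.
#' @return surface area in square metres (vectorised).
#' @examples
#' frustum_surface(0.33, 0.33, 5)  # cylinder: pi * 0.33 * 5
#' @export
frustum_surface <- function(d1_m, d2_m, length_m, ends = FALSE) {
  if (anyNA(c(d1_m, d2_m, length_m)) || any(d1_m <= 0 | d2_m <= 0 | length_m <= 0)) {
    stop("diameters and length must be positive")
  }
  r1 <- d1_m / 2
  r2 <- d2_m / 2
  a <- pi * (r1 + r2) * sqrt(length_m^2 + (r1 - r2)^2)
  if (ends) a <- a + pi * (r1^2 + r2^2)
  a
}
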