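# Species-level fruit-body traits: size, toughness coding, trait-table
# assembly and validation.

LINEAGES <- c("Basidiomycota", "Ascomycota")
FB_TYPES <- c("pileate-stipitate", "pileate-sessile", "perithecia", "apothecia")
BASIDIO_FB_TYPES <- c("pileate-stipitate", "pileate-sessile")
ASCO_FB_TYPES <- c("perithecia", "apothecia")
TOUGH_ORDERS <- c("Polyporales", "Gloeophyllales", "Hymenochaetales")
SOFT_ORDERS <- c("Agaricales")

#' Mean fruit-body size from literature minimum and maximum
#'
#' The size of a species is summarised as the arithmetic mean of the
#' minimum and maximum cap diameter (pileate-stipitate Basidiomycota,
#' apothecial Ascomycota) or fruit-body width (pileate-sessile
#' Basidiomycota, perithecial Ascomycota) reported in the literature.
#'
#' @param size_min_mm,size_max_mm numeric vectors of minimum and maximum
#'   diameter/width in millimetres; must be finite, non-negative and
#'   `size_min_mm <= size_max_mm` elementwise. `NA` pairs propagate to `NA`.
#' @param species_id optional character vector used to name offending
#'   species in error messages.
#' @return numeric vector of mean sizes in millimetres.
#' @examples
#' mean_fruit_body_size(20, 60)  # 40
#' @export
mean_fruit_body_size <- function(size_min_mm, size_max_mm, species_id = NULL) {
  stopifnot(length(size_min_mm) == length(size_max_mm))
  ids <- species_id
  if (is.null(ids)) ids <- paste0("record ", seq_along(size_min_mm))
  both <- !is.na(size_min_mm) & !is.na(size_max_mm)
  bad_neg <- both & (size_min_mm < 0 | size_max_mm < 0)
  if (any(bad_neg)) {
    stop("negative fruit-body size for: ", paste(ids[bad_neg], collapse = ", "))
  }
  bad_ord <- both & size_min_mm > size_max_mm
  if (any(bad_ord)) {
    stop("size_min_mm > size_max_mm for: ", paste(ids[bad_ord], collapse = ", "))
  }
  out <- rep(NA_real_, length(size_min_mm))
  out[both] <- (size_min_mm[both] + size_max_mm[both]) / 2
  out
}

#' Binary flesh-toughness coding from lineage and taxonomy
#'
#' Codes each species as tough- or soft-fleshed. Basidiomycota are coded
#' from the taxonomic order: Polyporales, Gloeophyllales and
#' Hymenochaetales are tough (di-/trimitic hyphal systems), Agaricales are
#' soft (monomitic); other orders get `NA` with a warning and must be
#' resolved by an explicit per-species override (see
#' [build_trait_table()]). Ascomycota are coded from the fruit-body type:
#' perithecia are tough, apothecia soft.
#'
#' @param lineage character vector, `"Basidiomycota"` or `"Ascomycota"`.
#' @param fb_type fruit-body type; required for Ascomycota.
#' @param taxon_order taxonomic order; required for Basidiomycota.
#' @return character vector with values `"tough"`, `"soft"` or `NA`.
#' @examples
#' code_toughness("Basidiomycota", "pileate-sessile", "Polyporales")  # tough
#' code_toughness("Ascomycota", "perithecia")                          # tough
#' @export
code_toughness <- function(lineage, fb_type = NULL, taxon_order = NULL) {
  n <- length(lineage)
  if (is.null(fb_type)) fb_type <- rep(NA_character_, n)
  if (is.null(taxon_order)) taxon_order <- rep(NA_character_, n)
  unknown <- !is.na(lineage) & !(lineage %in% LINEAGES)
  if (any(unknown)) {
    stop("unknown lineage: ", paste(unique(lineage[unknown]), collapse = ", "))
  }
  out <- rep(NA_character_, n)
  bas <- !is.na(lineage) & lineage == "Basidiomycota"
  out[bas & taxon_order %in% TOUGH_ORDERS] <- "tough"
  out[bas & taxon_order %in% SOFT_ORDERS] <- "soft"
  uncoded <- bas & !is.na(taxon_order) &
    !(taxon_order %in% c(TOUGH_ORDERS, SOFT_ORDERS))
  if (any(uncoded)) {
    warning("no order-level toughness rule for: ",
            paste(unique(taxon_order[uncoded]), collapse = ", "),
            "; supply an override table")
  }
  asc <- !is.na(lineage) & lineage == "Ascomycota"
  out[asc & fb_type == "perithecia"] <- "tough"
  out[asc & fb_type == "apothecia"] <- "soft"
  out
}

#' Assemble and validate a species trait table
#'
#' Reads (or takes) a species trait table, validates the lineage /
#' fruit-body-type pairing, derives the mean fruit-body size, codes
#' toughness from the order-level rule where it is not already supplied,
#' and applies an optional per-species toughness override table (needed
#' for Basidiomycota orders outside the four with a published rule).
#' Missing trait values are kept as `NA`: a species missing one trait is
#' only excluded from that trait's community mean downstream, never from
#' the community matrix.
#'
#' @param traits a data frame or path to a CSV file with columns
#'   `species_id`, `lineage`, `fb_type`, and optionally `taxon_order`,
#'   `size_min_mm`, `size_max_mm`, `lightness_pct`, `toughness`. Missing
#'   values are empty cells / `NA`.
#' @param overrides optional data frame or CSV path with columns
#'   `species_id`, `toughness` giving expert per-species toughness calls
#'   that take precedence over the order-level rule.
#' @param lightness optional data frame with columns `species_id`,
#'   `lightness_pct` (e.g. from [extract_species_lightness()]); fills the
#'   `lightness_pct` column where missing.
#' @return a `data.frame` with one row per species and columns
#'   `species_id`, `lineage`, `fb_type`, `taxon_order`, `size_min_mm`,
#'   `size_max_mm`, `size_mm`, `lightness_pct`, `toughness`.
#' @examples
#' f <- system.file("extdata", "example_traits.csv", package = "mycotraits")
#' tr <- build_trait_table(f)
#' tr[, c("species_id", "size_mm", "toughness")]
#' @export
build_trait_table <- function(traits, overrides = NULL, lightness = NULL) {
  tr <- if (is.character(traits)) read.csv(traits, stringsAsFactors = FALSE) else as.data.frame(traits)
  # empty CSV cells mean missing
  for (col in names(tr)) {
    if (is.character(tr[[col]])) tr[[col]][!nzchar(trimws(tr[[col]]))] <- NA
  }
  need <- c("species_id", "lineage", "fb_type")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trait table lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("taxon_order", "size_min_mm", "size_max_mm", "lightness_pct", "toughness")) {
    if (!col %in% names(tr)) tr[[col]] <- NA
  }
  if (anyDuplicated(tr$species_id)) {
    stop("duplicated species_id: ",
         paste(unique(tr$species_id[duplicated(tr$species_id)]), collapse = ", "))
  }
  bad_lin <- !tr$lineage %in% LINEAGES
  if (any(bad_lin)) stop("unknown lineage for: ", paste(tr$species_id[bad_lin], collapse = ", "))
  bad_fb <- !is.na(tr$fb_type) & !tr$fb_type %in% FB_TYPES
  if (any(bad_fb)) stop("unknown fb_type for: ", paste(tr$species_id[bad_fb], collapse = ", "))
  mismatch <- !is.na(tr$fb_type) &
    ((tr$lineage == "Basidiomycota" & !tr$fb_type %in% BASIDIO_FB_TYPES) |
     (tr$lineage == "Ascomycota" & !tr$fb_type %in% ASCO_FB_TYPES))
  if (any(mismatch)) {
    stop("fb_type inconsistent with lineage for: ",
         paste(tr$species_id[mismatch], collapse = ", "))
  }
  tr$size_mm <- mean_fruit_body_size(tr$size_min_mm, tr$size_max_mm, tr$species_id)

  if (!is.null(lightness)) {
    li <- as.data.frame(lightness)
    idx <- match(tr$species_id, li$species_id)
    fill <- is.na(tr$lightness_pct) & !is.na(idx)
    tr$lightness_pct[fill] <- li$lightness_pct[idx[fill]]
  }
  bad_light <- !is.na(tr$lightness_pct) & (tr$lightness_pct < 0 | tr$lightness_pct > 100)
  if (any(bad_light)) {
    stop("lightness_pct outside [0, 100] for: ",
         paste(tr$species_id[bad_light], collapse = ", "))
  }

  code <- is.na(tr$toughness)
  if (any(code)) {
    tr$toughness[code] <- code_toughness(tr$lineage[code], tr$fb_type[code],
                                         tr$taxon_order[code])
  }
  if (!is.null(overrides)) {
    ov <- if (is.character(overrides)) read.csv(overrides, stringsAsFactors = FALSE) else as.data.frame(overrides)
    idx <- match(tr$species_id, ov$species_id)
    hit <- !is.na(idx)
    tr$toughness[hit] <- ov$toughness[idx[hit]]
  }
  bad_t <- !is.na(tr$toughness) & !tr$toughness %in% c("soft", "tough")
  if (any(bad_t)) stop("toughness must be 'soft' or 'tough' for: ",
                       paste(tr$species_id[bad_t], collapse = ", "))
  tr[c("species_id", "lineage", "fb_type", "taxon_order",
       "size_min_mm", "size_max_mm", "size_mm", "lightness_pct", "toughness")]
}
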