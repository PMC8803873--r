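# Shared fixtures: a reduced experimental design for fast tests and a few
# hand-written matrices with known properties.

# 2 blocks x 8 plots (balanced beech/fir, no mixed plots), 30 species.
# The baseline log-odds is raised so the smaller pool still yields per-log
# richness comparable to the full design (~5-10 species).
small_cfg <- function(...) {
  args <- list(...)
  if (!"b0" %in% names(args)) args$b0 <- -1.9
  do.call(generator_config,
          c(list(n_blocks = 2, plots_per_block = 8, n_species = 30,
                 p_basidio = 0.6), args))
}

# Tiny deterministic trait table: sizes are powers of ten, lightness
# chosen so log10 is exact, toughness half and half.
toy_traits <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4"),
    lineage = c("Basidiomycota", "Basidiomycota", "Ascomycota", "Ascomycota"),
    fb_type = c("pileate-stipitate", "pileate-sessile", "perithecia", "apothecia"),
    taxon_order = c("Agaricales", "Polyporales", NA, NA),
    size_mm = c(10, 1000, 100, 10),
    lightness_pct = c(10, 100, 10, 100),
    toughness = c("soft", "tough", "tough", "soft"),
    stringsAsFactors = FALSE)
}

# Enumerate every binary matrix with the marginals of m0 (brute force);
# returns a character vector of serialized matrices (the fill class).
enumerate_fill_class <- function(m0) {
  n <- length(m0)
  rs <- rowSums(m0); cs <- colSums(m0)
  out <- character(0)
  for (code in 0:(2^n - 1)) {
    x <- matrix(as.integer(intToBits(code)[1:n]), nrow(m0), ncol(m0))
    if (all(rowSums(x) == rs) && all(colSums(x) == cs)) {
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

matrix_key <- function(m) paste(m, collapse = "")

# Community-from-scratch helper used across tests.
sim_community <- function(cfg, seed, min_richness = 3) {
  sim <- simulate_experiment(cfg, seed = seed)
  m <- suppressMessages(aggregate_years(sim$records, meta = sim$meta))
  list(sim = sim, m = m, mf = filter_min_richness(m, min_richness))
}
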