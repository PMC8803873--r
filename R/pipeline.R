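# End-to-end analysis: community assembly -> observed community traits ->
# null-model SES -> mixed-model / GLM inference, with a reproducible
# manifest and optional CSV output.

#' Run the full community trait / microclimate analysis
#'
#' Orchestrates every stage on real or synthetic data: aggregates survey
#' records into a presence/absence matrix (first year excluded), filters
#' logs by minimum richness, computes observed community trait means for
#' the full matrix and per lineage, derives independent-swap SES for every
#' scope, screens collinearity, fits the overall canopy LMEs (observed and
#' SES responses through the identical code path), lineage difference
#' tests, lineage-by-tree canopy contrasts, and the binomial canopy GLM.
#'
#' @param records occurrence records (`year`, `log_id`, `species_id`), or
#'   `NULL` to simulate.
#' @param meta log metadata; `NULL` to simulate.
#' @param traits species trait table; `NULL` to simulate.
#' @param synth_cfg a [generator_config()] used when data are simulated.
#' @param seed master seed: fanned out to the generator and the null-model
#'   randomizations; a run with the same inputs, config and seed is fully
#'   reproducible.
#' @param min_richness per-log richness threshold (default 3).
#' @param n_rand null-model randomizations (default 100).
#' @param exclude_years years dropped at aggregation (default: first year).
#' @param surface surface covariate handling for the LMEs (see
#'   [fit_trait_lme()]); `"none"` reproduces the final-model choice.
#' @param out_dir optional directory: writes `ctraits_*.csv`, `ses_*.csv`,
#'   `table1.csv`, `glm.csv`, `collinearity.csv` and `manifest.json`.
#' @return an object of class `mt_analysis`; see [print.mt_analysis()].
#' @export
run_full_analysis <- function(records = NULL, meta = NULL, traits = NULL,
                              synth_cfg = generator_config(), seed = 1,
                              min_richness = 3, n_rand = 100,
                              exclude_years = NULL,
                              surface = c("none", "sampled", "total", "both"),
                              out_dir = NULL) {
  surface <- match.arg(surface)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 5)
  synthetic <- is.null(records)
  if (synthetic) {
    sim <- simulate_experiment(synth_cfg, seed = seeds[1])
    records <- sim$records; meta <- sim$meta; traits <- sim$traits
  }
  m <- aggregate_years(records, exclude_years = exclude_years, meta = meta)
  m_filt <- filter_min_richness(m, min_richness)

  scopes <- c("all", "Basidiomycota", "Ascomycota")
  ctraits <- lapply(setNames(scopes, scopes), function(sc)
    community_trait_means(m, traits, lineage_scope = sc, min_richness = min_richness))
  ses <- vector("list", length(scopes)); names(ses) <- scopes
  for (i in seq_along(scopes)) {
    sc <- scopes[i]
    msc <- m
    if (sc != "all") {
      keep <- colnames(m) %in% traits$species_id[traits$lineage == sc]
      msc <- m[, keep, drop = FALSE]
    }
    msc <- filter_min_richness(msc, min_richness)
    ses[[sc]] <- ses_community_traits(msc, traits, n_rand = n_rand,
                                      seed = seeds[1 + i])
  }

  collin <- collinearity_check(ctraits$all)
  trait_names <- c("size", "lightness", "toughness")
  overall <- list(
    obs = lapply(setNames(trait_names, trait_names), function(t)
      fit_trait_lme(ctraits$all, meta, t, "obs", surface = surface)),
    ses = lapply(setNames(trait_names, trait_names), function(t)
      fit_trait_lme(ses$all, meta, t, "ses", surface = surface)))
  by_lin_obs <- list(Basidiomycota = ctraits$Basidiomycota,
                     Ascomycota = ctraits$Ascomycota)
  by_lin_ses <- list(Basidiomycota = ses$Basidiomycota,
                     Ascomycota = ses$Ascomycota)
  contrasts <- list(
    obs = lapply(setNames(trait_names, trait_names), function(t)
      lineage_contrasts(by_lin_obs, meta, t, "obs")),
    ses = lapply(setNames(trait_names, trait_names), function(t)
      lineage_contrasts(by_lin_ses, meta, t, "ses")))
  lineage_tests <- list(
    obs = lapply(setNames(trait_names, trait_names), function(t)
      lineage_difference_test(by_lin_obs, meta, t, "obs")),
    ses = lapply(setNames(trait_names, trait_names), function(t)
      lineage_difference_test(by_lin_ses, meta, t, "ses")))
  glm_fit <- list(obs = fit_canopy_glm(ctraits$all, meta, "obs"),
                  ses = fit_canopy_glm(ses$all, meta, "ses"))

  tab1 <- .assemble_table1(overall, contrasts)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mycotraits")),
    seed = seed, min_richness = min_richness, n_rand = n_rand,
    synthetic = synthetic,
    n_logs_total = nrow(m), n_logs_filtered = nrow(m_filt),
    n_species = ncol(m),
    generator = if (synthetic) unclass(synth_cfg) else NULL)

  res <- structure(list(matrix = m, matrix_filtered = m_filt,
                        ctraits = ctraits, ses = ses,
                        collinearity = collin, overall = overall,
                        contrasts = contrasts, lineage_tests = lineage_tests,
                        glm = glm_fit, table1 = tab1, meta = meta,
                        traits = traits, manifest = manifest),
                   class = "mt_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

# Table-1-shaped summary: Wald z per term/contrast, one OBS and one SES
# column per trait.
.assemble_table1 <- function(overall, contrasts) {
  trait_names <- c("size", "lightness", "toughness")
  term_z <- function(fit, term) {
    i <- match(term, fit$coefficients$term)
    if (is.na(i)) NA_real_ else fit$coefficients$z[i]
  }
  cov_term <- c(size = "mean_log10_size", lightness = "mean_log10_lightness",
                toughness = "prop_tough_asin")
  ses_term <- c(size = "ses_size", lightness = "ses_lightness",
                toughness = "ses_toughness")
  rows <- c("Intercept", "Canopy openness - open", "Tree species",
            "Size", "Lightness", "Toughness",
            "Basidiomycota - Canopy - Open",
            "Basidiomycota - Beech - Canopy - Open",
            "Basidiomycota - Fir - Canopy - Open",
            "Ascomycota - Canopy - Open",
            "Ascomycota - Beech - Canopy - Open",
            "Ascomycota - Fir - Canopy - Open")
  out <- data.frame(term = rows, stringsAsFactors = FALSE)
  contrast_z <- function(ct, lin, tr) {
    co <- ct$contrasts
    i <- which(co$lineage == lin & co$tree == tr)
    if (length(i) != 1) NA_real_ else co$z[i]
  }
  for (t in trait_names) {
    for (ty in c("obs", "ses")) {
      fit <- overall[[ty]][[t]]
      term_of <- if (ty == "obs") cov_term else ses_term
      col <- c(
        term_z(fit, "(Intercept)"),
        term_z(fit, "canopyopen"),
        term_z(fit, "treefir"),
        if (t == "size") NA_real_ else term_z(fit, term_of[["size"]]),
        if (t == "lightness") NA_real_ else term_z(fit, term_of[["lightness"]]),
        if (t == "toughness") NA_real_ else term_z(fit, term_of[["toughness"]]),
        contrast_z(contrasts[[ty]][[t]], "Basidiomycota", "all"),
        contrast_z(contrasts[[ty]][[t]], "Basidiomycota", "beech"),
        contrast_z(contrasts[[ty]][[t]], "Basidiomycota", "fir"),
        contrast_z(contrasts[[ty]][[t]], "Ascomycota", "all"),
        contrast_z(contrasts[[ty]][[t]], "Ascomycota", "beech"),
        contrast_z(contrasts[[ty]][[t]], "Ascomycota", "fir"))
      out[[paste0(t, "_", ty, "_z")]] <- col
    }
  }
  r2row <- data.frame(term = "Marginal R2", stringsAsFactors = FALSE)
  for (t in trait_names) for (ty in c("obs", "ses")) {
    r2row[[paste0(t, "_", ty, "_z")]] <- overall[[ty]][[t]]$r2_marginal
  }
  rbind(out, r2row)
}

#' Write all analysis outputs as CSV plus a JSON manifest
#'
#' @param x an `mt_analysis` object.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in names(x$ctraits)) {
    write.csv(x$ctraits[[sc]], file.path(out_dir, paste0("ctraits_", sc, ".csv")),
              row.names = FALSE)
    write.csv(x$ses[[sc]], file.path(out_dir, paste0("ses_", sc, ".csv")),
              row.names = FALSE)
  }
  write.csv(x$table1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  write.csv(rbind(cbind(model = "obs", x$glm$obs$coefficients),
                  cbind(model = "ses", x$glm$ses$coefficients)),
            file.path(out_dir, "glm.csv"), row.names = FALSE)
  write.csv(as.data.frame(x$collinearity$r),
            file.path(out_dir, "collinearity.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out_dir)
}

#' @export
print.mt_analysis <- function(x, digits = 2, ...) {
  cat("Community fruit-body trait analysis\n")
  cat(sprintf("  %d logs (%d passing the %s-species filter), %d species\n",
              x$manifest$n_logs_total, x$manifest$n_logs_filtered,
              x$manifest$min_richness, x$manifest$n_species))
  cat(sprintf("  null model: independent swap, %d randomizations\n",
              x$manifest$n_rand))
  cat("\nWald z by term (columns: trait_response):\n")
  tab <- x$table1
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mt_analysis <- function(object, ...) {
  x <- object
  cat("== Collinearity screen ==\n")
  print(x$collinearity)
  cat("\n== Overall canopy LMEs ==\n")
  for (ty in c("obs", "ses")) for (t in names(x$overall[[ty]])) print(x$overall[[ty]][[t]])
  cat("\n== Lineage difference tests (z for lineage term) ==\n")
  for (t in names(x$lineage_tests$obs)) {
    zo <- x$lineage_tests$obs[[t]]$coefficients
    z <- zo$z[grepl("^lineage", zo$term)]
    cat(sprintf("  %-10s z = %6.2f\n", t, z))
  }
  cat("\n== Binomial GLM of canopy on the three community traits ==\n")
  print(x$glm$obs)
  print(x$glm$ses)
  invisible(x)
}

#' Diagnostic plot of community traits by canopy
#'
#' Boxplots of the three observed community trait means under closed and
#' open canopies (overall scope).
#'
#' @param x an `mt_analysis`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.mt_analysis <- function(x, ...) {
  df <- merge(x$ctraits$all, x$meta, by = "log_id")
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::boxplot(mean_log10_size ~ canopy, data = df,
                    ylab = "mean log10 size (mm)", ...)
  graphics::boxplot(mean_log10_lightness ~ canopy, data = df,
                    ylab = "mean log10 lightness (%)", ...)
  graphics::boxplot(prop_tough ~ canopy, data = df,
                    ylab = "proportion tough-fleshed", ...)
  invisible(x)
}
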