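# Synthetic dead-wood experiment generator: species pool with
# lineage-structured traits, blocked plot design, and a logistic
# fruiting-occurrence model with controllable trait x canopy selection.

#' Configuration of the synthetic dead-wood experiment
#'
#' Bundles the design constants of the field experiment (5 blocks of 24
#' plots, half open / half closed canopy, half low / half high local
#' dead-wood amount, two sampled logs per plot, two host tree species,
#' a ~107-species pool in two lineages) with the parameters of an invented
#' fruiting-occurrence model used to simulate communities. Occurrence of
#' species `j` on log `i` (over the retained survey years) is Bernoulli with
#' `logit(p_ij) = b0 + u_species(j) + u_plot(i) + open_i * (beta_tough_open
#' * tough_j + beta_size_open * z(log10 size_j) + beta_light_open *
#' z(log10 lightness_j)) + beta_tree * [tree_i == preferred tree_j]`.
#' In the neutral setting the linear predictor is additive in a log effect
#' and a species effect, so conditionally on the matrix margins the
#' community is a uniform draw from the fill class — exactly the null
#' hypothesis of the independent-swap model.
#' All selection coefficients default to zero (the neutral setting used
#' for calibration); positive `beta_tough_open` enriches tough-fleshed
#' species under open canopies.
#'
#' @param n_blocks,plots_per_block,logs_sampled_per_plot design constants
#'   (defaults 5, 24, 2: 120 plots, 240 sampled logs).
#' @param n_species,p_basidio species-pool size and Basidiomycota share
#'   (defaults 107 and 60/107).
#' @param size_meanlog10,size_sdlog10 per-lineage mean and SD of log10
#'   fruit-body size (mm); Basidiomycota are markedly larger.
#' @param lightness_mean,lightness_sd per-lineage lightness (percent),
#'   truncated to (0, 100]; Ascomycota darker.
#' @param p_tough per-lineage probability of a tough-fleshed species.
#' @param n_missing_size,n_missing_lightness species left without the
#'   trait (defaults 1 and 2, mirroring typical literature-trait gaps).
#' @param b0 baseline occurrence log-odds per species-log pair (default
#'   -3.2, yielding a median per-log richness of about 5-10 and well over
#'   70 percent of logs passing the three-species filter).
#' @param sigma_species,sigma_plot SDs of species and plot random effects.
#' @param beta_tough_open,beta_size_open,beta_light_open trait-by-canopy
#'   selection coefficients (log-odds scale).
#' @param beta_tree host-tree preference coefficient.
#' @param years survey years; the first is excluded at aggregation.
#' @param log_diam_mean,log_diam_sd,log_length_m log dimensions (m).
#' @return a list of class `mt_generator_config`.
#' @export
generator_config <- function(n_blocks = 5, plots_per_block = 24,
                             logs_sampled_per_plot = 2,
                             n_species = 107, p_basidio = 60 / 107,
                             size_meanlog10 = c(Basidiomycota = 1.6, Ascomycota = 0.4),
                             size_sdlog10 = c(Basidiomycota = 0.45, Ascomycota = 0.45),
                             lightness_mean = c(Basidiomycota = 62, Ascomycota = 45),
                             lightness_sd = c(Basidiomycota = 15, Ascomycota = 15),
                             p_tough = c(Basidiomycota = 0.6, Ascomycota = 0.4),
                             n_missing_size = 1, n_missing_lightness = 2,
                             b0 = -3.2, sigma_species = 1.0, sigma_plot = 0.4,
                             beta_tough_open = 0, beta_size_open = 0,
                             beta_light_open = 0, beta_tree = 0.5,
                             years = 2012:2015,
                             log_diam_mean = 0.33, log_diam_sd = 0.065,
                             log_length_m = 5) {
  cfg <- as.list(environment())
  probs <- c(p_basidio, p_tough)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (plots_per_block %% 4 != 0) stop("plots_per_block must be divisible by 4")
  if (n_blocks < 1 || n_species < 2) stop("invalid design size")
  structure(cfg, class = "mt_generator_config")
}

.rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic species pool with lineage-structured traits
#'
#' Draws `n_species` species split between Basidiomycota and Ascomycota,
#' with log-normal fruit-body sizes, truncated-normal lightness, and
#' Bernoulli toughness per lineage. Fruit-body types and taxonomic orders
#' are assigned consistently with the toughness coding rule (perithecia /
#' polypore-type orders tough, apothecia / Agaricales soft), so re-coding
#' the pool with [code_toughness()] reproduces the drawn toughness.
#' A literature-style minimum/maximum size pair straddles each drawn mean.
#'
#' @param cfg a [generator_config()].
#' @param seed optional integer seed.
#' @return a trait table as produced by [build_trait_table()].
#' @export
generate_species_pool <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bas <- round(cfg$n_species * cfg$p_basidio)
  n_asc <- cfg$n_species - n_bas
  lineage <- rep(c("Basidiomycota", "Ascomycota"), c(n_bas, n_asc))
  n <- cfg$n_species
  tough <- rbinom(n, 1, cfg$p_tough[lineage]) == 1
  taxon_order <- ifelse(lineage == "Basidiomycota",
                        ifelse(tough,
                               sample(TOUGH_ORDERS, n, replace = TRUE),
                               "Agaricales"),
                        NA_character_)
  fb_type <- ifelse(lineage == "Basidiomycota",
                    ifelse(tough & runif(n) < 0.8, "pileate-sessile", "pileate-stipitate"),
                    ifelse(tough, "perithecia", "apothecia"))
  size <- 10^rnorm(n, cfg$size_meanlog10[lineage], cfg$size_sdlog10[lineage])
  size_min <- size * runif(n, 0.5, 0.9)
  size_max <- 2 * size - size_min
  light <- .rnorm_trunc(n, cfg$lightness_mean[lineage], cfg$lightness_sd[lineage],
                        lower = 1, upper = 100)
  if (cfg$n_missing_size > 0) {
    drop <- sample.int(n, min(cfg$n_missing_size, n))
    size_min[drop] <- NA; size_max[drop] <- NA
  }
  if (cfg$n_missing_lightness > 0) {
    drop <- sample.int(n, min(cfg$n_missing_lightness, n))
    light[drop] <- NA
  }
  build_trait_table(data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    lineage = lineage, fb_type = fb_type, taxon_order = taxon_order,
    size_min_mm = size_min, size_max_mm = size_max,
    lightness_pct = light,
    toughness = ifelse(tough, "tough", "soft"),
    stringsAsFactors = FALSE))
}

#' Generate the blocked plot and log metadata
#'
#' Lays out `n_blocks` blocks of `plots_per_block` plots, split half open /
#' half closed canopy and, within canopy, half low / half high local
#' dead-wood amount. Each block-canopy-amount cell holds equal numbers of
#' beech-only, fir-only and mixed plots. Two logs per plot are sampled;
#' log dimensions are drawn around 33 cm diameter x 5 m length and
#' surfaces use the truncated-cone formula. The whole-plot dead-wood
#' surface sums 4 (low) or 40 (high) local logs.
#'
#' @inheritParams generate_species_pool
#' @return a `data.frame` with one row per sampled log: `log_id`, `block`,
#'   `plot_id`, `canopy`, `tree`, `deadwood_amount`, `length_m`, `d1_m`,
#'   `d2_m`, `surface_m2` (the log), `surface_plot_m2` (all local logs).
#' @export
generate_deadwood_metadata <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per_cell <- cfg$plots_per_block / 4
  comp_pool <- rep(c("beech", "fir", "mixed"), length.out = per_cell)
  rows <- list()
  for (b in seq_len(cfg$n_blocks)) {
    idx <- 0
    for (canopy in c("closed", "open")) {
      for (amount in c("low", "high")) {
        for (cp in comp_pool) {
          idx <- idx + 1
          plot_id <- sprintf("b%dp%02d", b, idx)
          n_logs <- cfg$logs_sampled_per_plot
          trees <- switch(cp,
                          beech = rep("beech", n_logs),
                          fir = rep("fir", n_logs),
                          mixed = rep(c("beech", "fir"), length.out = n_logs))
          n_local <- if (amount == "low") 4 else 40
          d1 <- .rnorm_trunc(n_local, cfg$log_diam_mean, cfg$log_diam_sd, 0.05, 1)
          d2 <- .rnorm_trunc(n_local, cfg$log_diam_mean, cfg$log_diam_sd, 0.05, 1)
          surf <- frustum_surface(d1, d2, cfg$log_length_m)
          rows[[length(rows) + 1]] <- data.frame(
            log_id = sprintf("%s_l%d", plot_id, seq_len(n_logs)),
            block = b, plot_id = plot_id, canopy = canopy, tree = trees,
            deadwood_amount = amount, length_m = cfg$log_length_m,
            d1_m = d1[seq_len(n_logs)], d2_m = d2[seq_len(n_logs)],
            surface_m2 = surf[seq_len(n_logs)],
            surface_plot_m2 = sum(surf),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate fruiting occurrence records on the sampled logs
#'
#' Draws one Bernoulli occurrence per species x sampled log under the
#' logistic occupancy model described in [generator_config()], then
#' scatters each realized occurrence over the survey years (every present
#' pair is recorded in at least one retained year; records confined to the
#' excluded first year never occur for absent pairs). Species and plot
#' random effects create the occupancy and richness heterogeneity the
#' fixed-marginal null model conditions on; the trait-by-canopy selection
#' coefficients inject (or, at zero, withhold) a non-random trait pattern.
#'
#' @param pool trait table from [generate_species_pool()].
#' @param meta metadata from [generate_deadwood_metadata()].
#' @inheritParams generate_species_pool
#' @return a long `data.frame` of occurrence records with columns `year`,
#'   `log_id`, `species_id`.
#' @export
generate_occurrences <- function(pool, meta, cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sp <- nrow(pool)
  n_log <- nrow(meta)
  u_sp <- rnorm(n_sp, 0, cfg$sigma_species)
  pref <- sample(c("beech", "fir"), n_sp, replace = TRUE)
  plots <- unique(meta$plot_id)
  u_plot <- setNames(rnorm(length(plots), 0, cfg$sigma_plot), plots)
  zs <- function(x) {
    z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    ifelse(is.na(z), 0, z)
  }
  z_size <- zs(log10(pool$size_mm))
  z_light <- zs(log10(pool$lightness_pct))
  tough <- as.numeric(!is.na(pool$toughness) & pool$toughness == "tough")
  open <- as.numeric(meta$canopy == "open")
  # logit matrix: logs x species
  sp_part <- matrix(cfg$b0 + u_sp, n_log, n_sp, byrow = TRUE)
  sel <- cfg$beta_tough_open * tough + cfg$beta_size_open * z_size +
    cfg$beta_light_open * z_light
  eta <- sp_part + u_plot[meta$plot_id] + outer(open, sel) +
    cfg$beta_tree * outer(meta$tree, pref, `==`)
  p <- plogis(eta)
  hit <- which(matrix(runif(n_log * n_sp), n_log, n_sp) < p, arr.ind = TRUE)
  n_hit <- nrow(hit)
  # scatter each occurrence over survey years: any year with prob 0.5,
  # forcing at least one retained (non-first) year
  years <- cfg$years
  retained <- years[-1]
  seen <- matrix(runif(n_hit * length(years)) < 0.5, n_hit, length(years))
  none_retained <- which(rowSums(seen[, -1, drop = FALSE]) == 0)
  if (length(none_retained)) {
    forced <- sample(seq_along(retained), length(none_retained), replace = TRUE)
    seen[cbind(none_retained, 1 + forced)] <- TRUE
  }
  idx <- which(seen, arr.ind = TRUE)
  out <- data.frame(year = years[idx[, 2]],
                    log_id = meta$log_id[hit[idx[, 1], 1]],
                    species_id = pool$species_id[hit[idx[, 1], 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$year, out$log_id, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic dead-wood experiment
#'
#' Convenience wrapper: species pool, metadata and occurrence records in
#' one call, with the master seed fanned out to independent sub-seeds for
#' each stage so stages are individually reproducible.
#'
#' @inheritParams generate_species_pool
#' @return list with elements `traits`, `meta`, `records`, `cfg`, `seed`.
#' @export
simulate_experiment <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)
  traits <- generate_species_pool(cfg, seed = seeds[1])
  meta <- generate_deadwood_metadata(cfg, seed = seeds[2])
  records <- generate_occurrences(traits, meta, cfg, seed = seeds[3])
  list(traits = traits, meta = meta, records = records, cfg = cfg, seed = seed)
}
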