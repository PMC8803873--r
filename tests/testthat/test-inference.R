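# Helpers to build a community-trait table with known structure on top of
# a balanced synthetic design (no mixed-tree plots, so tree is plot-level).
make_meta <- function(seed = 1) generate_deadwood_metadata(small_cfg(), seed = seed)

make_ctraits <- function(meta, canopy_effect = c(size = 0, lightness = 0, toughness = 0),
                         sd = 0.2, seed = 1) {
  set.seed(seed)
  open <- as.numeric(meta$canopy == "open")
  n <- nrow(meta)
  p <- plogis(qlogis(0.5) + canopy_effect[["toughness"]] * open + rnorm(n, 0, sd))
  data.frame(
    log_id = meta$log_id,
    richness = 5L,
    mean_log10_size = 1 + canopy_effect[["size"]] * open + rnorm(n, 0, sd),
    mean_log10_lightness = 1.7 + canopy_effect[["lightness"]] * open + rnorm(n, 0, sd),
    prop_tough = p,
    prop_tough_asin = asin(sqrt(p)),
    stringsAsFactors = FALSE)
}

test_that("collinearity screen flags strong and undefined correlations", {
  meta <- make_meta()
  ct <- make_ctraits(meta)
  ct$mean_log10_lightness <- -ct$mean_log10_size          # r = -1
  rep <- collinearity_check(ct)
  expect_equal(diag(rep$r), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(rep$r["mean_log10_size", "mean_log10_lightness"], -1)
  expect_true(any(rep$flagged$var1 == "mean_log10_size" &
                    rep$flagged$var2 == "mean_log10_lightness"))
  ct2 <- make_ctraits(meta)
  ct2$prop_tough_asin <- 0.5                              # constant -> undefined
  rep2 <- collinearity_check(ct2)
  expect_true(is.na(rep2$r["mean_log10_size", "prop_tough_asin"]))
  expect_true(nrow(rep2$flagged) >= 2)
  expect_error(collinearity_check(ct[1:2, ]), "at least 3")
})

test_that("independent columns show negligible correlation at n = 1000", {
  set.seed(8)
  ct <- data.frame(log_id = 1:1000,
                   mean_log10_size = rnorm(1000),
                   mean_log10_lightness = rnorm(1000),
                   prop_tough_asin = rnorm(1000))
  expect_lt(collinearity_check(ct)$max_abs_r, 0.1)
})

test_that("the canopy LME recovers an injected effect with Wald z = estimate/se", {
  meta <- make_meta()
  ct <- make_ctraits(meta, canopy_effect = c(size = 0.5, lightness = 0, toughness = 0))
  fit <- fit_trait_lme(ct, meta, "size", "obs")
  co <- fit$coefficients
  i <- match("canopyopen", co$term)
  expect_equal(co$estimate[i], 0.5, tolerance = 0.15)
  expect_equal(co$z, co$estimate / co$se)
  expect_equal(co$p, 2 * pnorm(-abs(co$z)))
  expect_true(fit$r2_marginal >= 0 && fit$r2_marginal <= 1)
})

test_that("Wald z of slopes is invariant to affine rescaling of the response", {
  meta <- make_meta()
  ct <- make_ctraits(meta, canopy_effect = c(size = 0.3, lightness = 0, toughness = 0))
  f1 <- fit_trait_lme(ct, meta, "size", "obs")
  ct2 <- ct
  ct2$mean_log10_size <- 3 * ct$mean_log10_size + 2
  f2 <- fit_trait_lme(ct2, meta, "size", "obs")
  i <- f1$coefficients$term != "(Intercept)"
  expect_equal(f1$coefficients$z[i], f2$coefficients$z[i], tolerance = 1e-6)
})

test_that("degenerate responses and constant covariates are flagged, not fatal", {
  meta <- make_meta()
  ct <- make_ctraits(meta)
  ct$mean_log10_size <- 1.5
  expect_warning(fit <- fit_trait_lme(ct, meta, "size", "obs"), "constant")
  expect_equal(fit$coefficients$estimate[-1], rep(0, nrow(fit$coefficients) - 1))
  expect_true(all(is.na(fit$coefficients$z[-1])))
  ct2 <- make_ctraits(meta)
  ct2$mean_log10_lightness <- 1.7   # constant covariate in the size model
  expect_warning(fit2 <- fit_trait_lme(ct2, meta, "size", "obs"),
                 "dropping constant model term")
  expect_false("mean_log10_lightness" %in% fit2$coefficients$term)
})

test_that("surface covariates can be retained or dropped by configuration", {
  meta <- make_meta()
  ct <- make_ctraits(meta)
  f_none <- fit_trait_lme(ct, meta, "size", "obs", surface = "none")
  f_both <- fit_trait_lme(ct, meta, "size", "obs", surface = "both")
  expect_false(any(grepl("surface", f_none$coefficients$term)))
  expect_true(all(c("surface_m2", "surface_plot_m2") %in% f_both$coefficients$term))
})

stack_lineage_tables <- function(seed, delta_bas = 0, delta_asc = 0) {
  meta <- make_meta(seed)
  ct_b <- make_ctraits(meta, canopy_effect = c(size = delta_bas, lightness = 0, toughness = 0),
                       seed = seed)
  ct_a <- make_ctraits(meta, canopy_effect = c(size = delta_asc, lightness = 0, toughness = 0),
                       seed = seed + 1000)
  list(meta = meta, tabs = list(Basidiomycota = ct_b, Ascomycota = ct_a))
}

test_that("lineage canopy contrasts match the emmeans oracle", {
  library(emmeans)
  x <- stack_lineage_tables(3, delta_bas = 0.4, delta_asc = -0.4)
  lc <- lineage_contrasts(x$tabs, x$meta, "size", "obs")
  fit <- lc$fit$fit
  em1 <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ canopy | lineage, lmer.df = "asymptotic"),
    method = "revpairwise"))
  co <- lc$contrasts[lc$contrasts$tree == "all", ]
  for (lin in c("Ascomycota", "Basidiomycota")) {
    mine <- co[co$lineage == lin, ]
    theirs <- em1[em1$lineage == lin, ]
    expect_equal(mine$estimate, theirs$estimate, tolerance = 1e-6)
    expect_equal(mine$se, theirs$SE, tolerance = 1e-6)
  }
  em2 <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ canopy | lineage * tree, lmer.df = "asymptotic"),
    method = "revpairwise"))
  co2 <- lc$contrasts[lc$contrasts$tree != "all", ]
  for (i in seq_len(nrow(co2))) {
    j <- which(em2$lineage == co2$lineage[i] & em2$tree == co2$tree[i])
    expect_equal(co2$estimate[i], em2$estimate[j], tolerance = 1e-6)
    expect_equal(co2$se[i], em2$SE[j], tolerance = 1e-6)
  }
})

test_that("opposite injected canopy effects are recovered with opposite signs", {
  hits <- vapply(1:10, function(s) {
    x <- stack_lineage_tables(s, delta_bas = 0.5, delta_asc = -0.5)
    co <- lineage_contrasts(x$tabs, x$meta, "size", "obs")$contrasts
    co <- co[co$tree == "all", ]
    co$estimate[co$lineage == "Basidiomycota"] > 0 &&
      co$estimate[co$lineage == "Ascomycota"] < 0
  }, logical(1))
  expect_true(mean(hits) >= 0.9)
})

test_that("single-lineage input and empty design cells are rejected or flagged", {
  x <- stack_lineage_tables(4)
  expect_error(lineage_contrasts(x$tabs["Basidiomycota"], x$meta, "size"),
               "both lineages")
  # empty Ascomycota x fir x open cell
  drop_logs <- x$meta$log_id[x$meta$tree == "fir" & x$meta$canopy == "open"]
  tabs <- x$tabs
  tabs$Ascomycota <- tabs$Ascomycota[!tabs$Ascomycota$log_id %in% drop_logs, ]
  lc <- suppressWarnings(lineage_contrasts(tabs, x$meta, "size", "obs"))
  co <- lc$contrasts
  expect_true(is.na(co$estimate[co$lineage == "Ascomycota" & co$tree == "fir"]))
  expect_true(is.na(co$estimate[co$lineage == "Ascomycota" & co$tree == "all"]))
  expect_false(is.na(co$estimate[co$lineage == "Basidiomycota" & co$tree == "fir"]))
})

test_that("lineage difference test recovers a large injected size difference", {
  signs <- vapply(1:5, function(s) {
    meta <- make_meta(s)
    ct_b <- make_ctraits(meta, seed = s)
    ct_a <- make_ctraits(meta, seed = s + 500)
    ct_b$mean_log10_size <- ct_b$mean_log10_size + 1   # 10x larger Basidiomycota
    fit <- lineage_difference_test(list(Basidiomycota = ct_b, Ascomycota = ct_a),
                                   meta, "size", "obs")
    co <- fit$coefficients
    co$estimate[co$term == "lineageBasidiomycota"] > 0 &&
      co$p[co$term == "lineageBasidiomycota"] < 0.001
  }, logical(1))
  expect_true(all(signs))
})

test_that("the canopy GLM ranks a toughness-driven signal above the other traits", {
  meta <- make_meta(6)
  set.seed(6)
  # canopy assigned by thresholding toughness alone
  ct <- make_ctraits(meta)
  meta$canopy <- ifelse(ct$prop_tough_asin + rnorm(nrow(meta), 0, 0.05) >
                          stats::median(ct$prop_tough_asin), "open", "closed")
  fit <- fit_canopy_glm(ct, meta)
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  zt <- abs(co$z[co$term == "prop_tough_asin"])
  expect_gt(co$z[co$term == "prop_tough_asin"], 0)
  expect_true(all(zt >= abs(co$z[co$term != "prop_tough_asin"])))
})

test_that("perfect separation is flagged in the canopy GLM", {
  meta <- make_meta(7)
  ct <- make_ctraits(meta, seed = 7)
  ct$prop_tough_asin <- ifelse(meta$canopy == "open", 1.2, 0.3)
  fit <- suppressWarnings(fit_canopy_glm(ct, meta))
  expect_true(fit$separation)
})
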