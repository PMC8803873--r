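# Mixed-model and GLM inference of canopy-openness effects on community
# traits, lineage contrasts, and the collinearity screen.

# ---- model-fit container ---------------------------------------------------

new_mt_fit <- function(coefficients, r2_marginal, model_kind, response,
                       fit = NULL, data = NULL, fixed_terms = NULL,
                       singular = FALSE, separation = FALSE) {
  structure(list(coefficients = coefficients, r2_marginal = r2_marginal,
                 model_kind = model_kind, response = response, fit = fit,
                 data = data, fixed_terms = fixed_terms, singular = singular,
                 separation = separation),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("%s fit of %s\n", toupper(x$model_kind), x$response))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 4)
  co$se <- signif(co$se, 4)
  co$z <- round(co$z, 2)
  co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  if (!is.na(x$r2_marginal)) cat(sprintf("marginal R2 = %.3f\n", x$r2_marginal))
  if (isTRUE(x$singular)) cat("note: random-effect variance at boundary (singular fit)\n")
  if (isTRUE(x$separation)) cat("note: possible complete separation\n")
  invisible(x)
}

#' @export
coef.mt_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

# ---- shared helpers --------------------------------------------------------

.as_analysis_factors <- function(df) {
  if ("canopy" %in% names(df)) df$canopy <- factor(df$canopy, levels = c("closed", "open"))
  if ("tree" %in% names(df)) df$tree <- factor(df$tree, levels = c("beech", "fir"))
  if ("lineage" %in% names(df)) df$lineage <- factor(df$lineage, levels = c("Ascomycota", "Basidiomycota"))
  if ("block" %in% names(df)) df$block <- factor(df$block)
  if ("plot_id" %in% names(df)) df$plot_id <- factor(df$plot_id)
  df
}

.join_meta <- function(ctraits, meta) {
  unjoined <- setdiff(ctraits$log_id, meta$log_id)
  if (length(unjoined)) stop("logs missing from metadata: ",
                             paste(unjoined, collapse = ", "))
  df <- merge(ctraits, meta, by = "log_id", sort = FALSE)
  .as_analysis_factors(df)
}

.response_cols <- function(type) {
  if (type == "obs") {
    c(size = "mean_log10_size", lightness = "mean_log10_lightness",
      toughness = "prop_tough_asin")
  } else {
    c(size = "ses_size", lightness = "ses_lightness", toughness = "ses_toughness")
  }
}

.drop_degenerate_terms <- function(df, fixed_terms) {
  keep <- vapply(fixed_terms, function(tm) {
    vars <- all.vars(as.formula(paste("~", tm)))
    for (v in vars) {
      col <- df[[v]]
      if (is.numeric(col) && (all(is.na(col)) || var(col, na.rm = TRUE) == 0)) return(FALSE)
      if ((is.factor(col) || is.character(col)) && length(unique(col[!is.na(col)])) < 2) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant model term(s): ", paste(fixed_terms[!keep], collapse = ", "))
  }
  fixed_terms[keep]
}

.wald_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * pnorm(abs(z), lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

# REML linear mixed model with plot-in-block random intercepts, Wald z
# inference and a variance-partition marginal R2.
.fit_lme_wald <- function(df, response, fixed_terms,
                          random = "(1 | block/plot_id)",
                          response_label = response) {
  used <- unique(c(response, unlist(lapply(fixed_terms, function(tm)
    all.vars(as.formula(paste("~", tm))))), all.vars(as.formula(paste("~", random)))))
  used <- intersect(used, names(df))
  df <- df[stats::complete.cases(df[used]), , drop = FALSE]
  df <- droplevels(df)
  if (nrow(df) < 3) stop("fewer than 3 complete observations for ", response_label)
  y <- df[[response]]
  if (var(y) == 0) {
    warning("response is constant; slope estimates set to 0, z undefined")
    co <- data.frame(term = c("(Intercept)", fixed_terms),
                     estimate = c(y[1], rep(0, length(fixed_terms))),
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    return(new_mt_fit(co, NA_real_, "lme", response_label, data = df,
                      fixed_terms = fixed_terms))
  }
  fixed_terms <- .drop_degenerate_terms(df, fixed_terms)
  if (!length(fixed_terms)) fixed_terms <- "1"
  fml <- as.formula(paste(response, "~", paste(fixed_terms, collapse = " + "),
                          "+", random))
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  sm <- summary(fit)$coefficients
  co <- .wald_table(setNames(sm[, "Estimate"], rownames(sm)), sm[, "Std. Error"])
  X <- model.matrix(fit)
  var_fixed <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_random <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_resid <- stats::sigma(fit)^2
  r2m <- var_fixed / (var_fixed + var_random + var_resid)
  new_mt_fit(co, r2m, "lme", response_label, fit = fit, data = df,
             fixed_terms = fixed_terms, singular = lme4::isSingular(fit))
}

# ---- collinearity screen ---------------------------------------------------

#' Pairwise collinearity screen of community trait means
#'
#' Computes all pairwise Pearson correlations among the (transformed)
#' community trait means and any extra covariates, and flags pairs at or
#' above the conventional `|r| >= 0.7` collinearity threshold. Constant
#' columns yield undefined correlations, which are flagged.
#'
#' @param ctraits a community trait table (see [community_trait_means()]).
#' @param covariates optional data frame of extra numeric covariates,
#'   aligned to `ctraits` rows (e.g. log surface areas).
#' @param threshold flagging threshold on `|r|` (default 0.7).
#' @return an object of class `mt_collinearity`: list with the correlation
#'   matrix `r`, `max_abs_r`, a data frame `flagged`, and `threshold`.
#' @export
collinearity_check <- function(ctraits, covariates = NULL, threshold = 0.7) {
  num <- ctraits[, intersect(c("mean_log10_size", "mean_log10_lightness",
                               "prop_tough_asin"), names(ctraits)), drop = FALSE]
  if (!is.null(covariates)) num <- cbind(num, as.data.frame(covariates))
  num <- as.data.frame(lapply(num, as.numeric))
  cc <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(cc) < 3) stop("need at least 3 complete rows")
  k <- ncol(cc)
  r <- diag(1, k)
  dimnames(r) <- list(names(cc), names(cc))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (sd(cc[[i]]) == 0 || sd(cc[[j]]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- cor(cc[[i]], cc[[j]])
      }
    }
  }
  off <- which(upper.tri(r), arr.ind = TRUE)
  flag <- is.na(r[off]) | abs(r[off]) >= threshold
  flagged <- data.frame(var1 = rownames(r)[off[flag, 1]],
                        var2 = colnames(r)[off[flag, 2]],
                        r = r[off][flag], stringsAsFactors = FALSE)
  structure(list(r = r, max_abs_r = suppressWarnings(max(abs(r[off]), na.rm = TRUE)),
                 flagged = flagged, threshold = threshold, n = nrow(cc)),
            class = "mt_collinearity")
}

#' @export
print.mt_collinearity <- function(x, ...) {
  cat("Pairwise Pearson correlations (n =", x$n, "complete rows)\n")
  print(round(x$r, 3))
  cat(sprintf("max |r| = %.3f (threshold %.2f)\n", x$max_abs_r, x$threshold))
  if (nrow(x$flagged)) {
    cat("flagged pairs:\n")
    print(x$flagged, row.names = FALSE)
  } else cat("no pair flagged\n")
  invisible(x)
}

# ---- canopy LME ------------------------------------------------------------

#' Linear mixed model of canopy openness on one community trait
#'
#' The "overall model": fits the community trait (observed transformed
#' mean, or its SES) against canopy openness with tree species and —
#' following the covariate-retention strategy — the other two community
#' trait means as fixed covariates, and nested random intercepts for plot
#' in block. Inference is Wald: `z = estimate / SE` referred to the
#' standard normal. The coefficient of determination is the marginal R2
#' (fixed-effect variance over total variance).
#'
#' @param ctraits community trait table (`type = "obs"`) or SES table from
#'   [ses_community_traits()] (`type = "ses"`).
#' @param meta log metadata with `log_id`, `block`, `plot_id`, `canopy`,
#'   `tree` (and optionally `surface_m2`, `surface_plot_m2`).
#' @param trait `"size"`, `"lightness"` or `"toughness"`.
#' @param type `"obs"` or `"ses"`.
#' @param include_tree include tree species as a fixed covariate.
#' @param include_covariates include the other two community trait means.
#' @param surface `"none"` (default, the final-model choice), `"sampled"`
#'   (per-log sampled surface), `"total"` (whole-plot dead-wood surface),
#'   or `"both"`.
#' @return an object of class `mt_fit`.
#' @export
fit_trait_lme <- function(ctraits, meta, trait = c("size", "lightness", "toughness"),
                          type = c("obs", "ses"), include_tree = TRUE,
                          include_covariates = TRUE,
                          surface = c("none", "sampled", "total", "both")) {
  trait <- match.arg(trait)
  type <- match.arg(type)
  surface <- match.arg(surface)
  cols <- .response_cols(type)
  df <- .join_meta(ctraits, meta)
  fixed <- "canopy"
  if (include_tree) fixed <- c(fixed, "tree")
  if (include_covariates) fixed <- c(fixed, unname(cols[setdiff(names(cols), trait)]))
  if (surface %in% c("sampled", "both")) fixed <- c(fixed, "surface_m2")
  if (surface %in% c("total", "both")) fixed <- c(fixed, "surface_plot_m2")
  .fit_lme_wald(df, cols[[trait]], fixed,
                response_label = paste0(trait, " (", toupper(type), ")"))
}

# ---- lineage models --------------------------------------------------------

.stack_lineages <- function(ct_by_lineage) {
  if (is.null(names(ct_by_lineage)) ||
      !all(names(ct_by_lineage) %in% c("Basidiomycota", "Ascomycota"))) {
    stop("ct_by_lineage must be a named list with elements 'Basidiomycota' and/or 'Ascomycota'")
  }
  if (length(ct_by_lineage) < 2) {
    stop("both lineages are required (single-lineage input: lineage terms inestimable)")
  }
  out <- do.call(rbind, lapply(names(ct_by_lineage), function(nm) {
    x <- as.data.frame(ct_by_lineage[[nm]])
    x$lineage <- nm
    x
  }))
  rownames(out) <- NULL
  out
}

#' Test lineage differences in a community trait
#'
#' Mixed model of a community trait on lineage (Basidiomycota vs
#' Ascomycota) with the other two community trait means as covariates and
#' plot-in-block random intercepts, on the lineage-specific community
#' trait tables stacked together.
#'
#' @param ct_by_lineage named list of per-lineage community trait (or SES)
#'   tables, names `"Basidiomycota"` and `"Ascomycota"`.
#' @inheritParams fit_trait_lme
#' @return an `mt_fit`.
#' @export
lineage_difference_test <- function(ct_by_lineage, meta,
                                    trait = c("size", "lightness", "toughness"),
                                    type = c("obs", "ses"),
                                    include_covariates = TRUE) {
  trait <- match.arg(trait)
  type <- match.arg(type)
  cols <- .response_cols(type)
  df <- .join_meta(.stack_lineages(ct_by_lineage), meta)
  fixed <- "lineage"
  if (include_covariates) fixed <- c(fixed, unname(cols[setdiff(names(cols), trait)]))
  .fit_lme_wald(df, cols[[trait]], fixed,
                response_label = paste0(trait, " (", toupper(type), "), lineage test"))
}

# Reference-grid canopy contrasts (open - closed) from the fixed-effect
# covariance matrix, least-squares-means style: factors crossed, numeric
# covariates held at their means, nuisance factor levels averaged with
# equal weight.
.canopy_contrasts <- function(fitobj, by) {
  fit <- fitobj$fit
  df <- fitobj$data
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  fml <- reformulate(fitobj$fixed_terms)
  fac <- c("lineage", "tree", "canopy")
  grid <- expand.grid(lapply(df[fac], levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  names(grid) <- fac
  for (f in fac) grid[[f]] <- factor(grid[[f]], levels = levels(df[[f]]))
  nums <- setdiff(all.vars(fml), fac)
  for (v in nums) grid[[v]] <- mean(df[[v]])
  X <- model.matrix(fml, grid)[, names(beta), drop = FALSE]
  cell_n <- function(sel) sum(Reduce(`&`, lapply(names(sel), function(f)
    df[[f]] == sel[[f]])))
  groups <- unique(grid[, by, drop = FALSE])
  res <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- groups[g, , drop = FALSE]
    in_g <- Reduce(`&`, lapply(by, function(f) grid[[f]] == sel[[f]]))
    open <- in_g & grid$canopy == "open"
    closed <- in_g & grid$canopy == "closed"
    L <- colMeans(X[open, , drop = FALSE]) - colMeans(X[closed, , drop = FALSE])
    # every design cell entering the contrast must be populated
    cells <- grid[in_g, setdiff(fac, "canopy"), drop = FALSE]
    ok <- all(vapply(seq_len(nrow(cells)), function(i) {
      cell_n(c(as.list(cells[i, , drop = FALSE]), list(canopy = "open"))) > 0 &&
        cell_n(c(as.list(cells[i, , drop = FALSE]), list(canopy = "closed"))) > 0
    }, logical(1)))
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    out <- as.data.frame(sel, stringsAsFactors = FALSE)
    out$estimate <- if (ok) est else NA_real_
    out$se <- if (ok) se else NA_real_
    out
  })
  res <- do.call(rbind, res)
  res$z <- res$estimate / res$se
  res$p <- 2 * pnorm(abs(res$z), lower.tail = FALSE)
  res
}

#' Canopy contrasts within lineages and lineage-by-tree cells
#'
#' Fits the full factorial mixed model `trait ~ lineage * tree * canopy`
#' (plus the other two community means as covariates) with plot-in-block
#' random intercepts on the stacked lineage-specific tables, then reports
#' least-squares-means-style canopy contrasts (open minus closed): one per
#' lineage (averaged over tree species with equal weight) and one per
#' lineage-by-tree cell, each with a Wald z from the fixed-effect
#' covariance matrix. Contrasts touching an empty design cell are `NA`.
#'
#' @inheritParams lineage_difference_test
#' @return an object of class `mt_contrasts`: list with `contrasts` (data
#'   frame with columns `lineage`, `tree`, `estimate`, `se`, `z`, `p`;
#'   `tree == "all"` rows are the within-lineage contrasts) and `fit`
#'   (the underlying `mt_fit`).
#' @export
lineage_contrasts <- function(ct_by_lineage, meta,
                              trait = c("size", "lightness", "toughness"),
                              type = c("obs", "ses"),
                              include_covariates = TRUE) {
  trait <- match.arg(trait)
  type <- match.arg(type)
  cols <- .response_cols(type)
  df <- .join_meta(.stack_lineages(ct_by_lineage), meta)
  fixed <- "lineage * tree * canopy"
  if (include_covariates) fixed <- c(fixed, unname(cols[setdiff(names(cols), trait)]))
  fitobj <- .fit_lme_wald(df, cols[[trait]], fixed,
                          response_label = paste0(trait, " (", toupper(type),
                                                  "), lineage x tree x canopy"))
  if (is.null(fitobj$fit)) stop("degenerate response; contrasts unavailable")
  by_lin <- .canopy_contrasts(fitobj, "lineage")
  by_lin$tree <- "all"
  by_cell <- .canopy_contrasts(fitobj, c("lineage", "tree"))
  by_cell$tree <- as.character(by_cell$tree)
  cols_out <- c("lineage", "tree", "estimate", "se", "z", "p")
  contrasts <- rbind(by_lin[cols_out], by_cell[cols_out])
  contrasts$lineage <- as.character(contrasts$lineage)
  structure(list(contrasts = contrasts, fit = fitobj,
                 response = fitobj$response), class = "mt_contrasts")
}

#' @export
print.mt_contrasts <- function(x, ...) {
  cat("Canopy contrasts (open - closed) for", x$response, "\n")
  co <- x$contrasts
  co$estimate <- signif(co$estimate, 4)
  co$se <- signif(co$se, 4)
  co$z <- round(co$z, 2)
  co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

# ---- binomial GLM ----------------------------------------------------------

#' Binomial GLM of canopy openness on all three community traits
#'
#' Logistic regression with canopy openness (open = 1) as the response and
#' the three community trait means as predictors in a single model, so
#' that the traits' Wald z values are directly comparable within one fit.
#'
#' @inheritParams fit_trait_lme
#' @param tree_interaction also include tree species and its interactions
#'   with the three predictors (`:` terms).
#' @param epsilon IRLS convergence tolerance passed to [stats::glm()].
#' @return an `mt_fit` with `model_kind = "glm_binomial"`; `separation` is
#'   `TRUE` when fitted probabilities of 0/1 indicate complete separation.
#' @export
fit_canopy_glm <- function(ctraits, meta, type = c("obs", "ses"),
                           tree_interaction = FALSE, epsilon = 1e-10) {
  type <- match.arg(type)
  cols <- .response_cols(type)
  df <- .join_meta(ctraits, meta)
  df$canopy_open <- as.integer(df$canopy == "open")
  preds <- unname(cols)
  terms_ <- preds
  if (tree_interaction) terms_ <- c(terms_, "tree", paste0("tree:", preds))
  used <- c("canopy_open", preds, if (tree_interaction) "tree")
  df <- df[stats::complete.cases(df[used]), , drop = FALSE]
  if (nrow(df) < length(preds) + 2) stop("too few complete rows for the GLM")
  terms_ <- .drop_degenerate_terms(df, terms_)
  fml <- reformulate(terms_, response = "canopy_open")
  fit <- glm(fml, family = binomial(), data = df,
             control = list(epsilon = epsilon, maxit = 100))
  sm <- summary(fit)$coefficients
  co <- .wald_table(setNames(sm[, "Estimate"], rownames(sm)), sm[, "Std. Error"])
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep) warning("fitted probabilities of 0 or 1: possible complete separation")
  new_mt_fit(co, NA_real_, "glm_binomial",
             paste0("canopy ~ traits (", toupper(type), ")"),
             fit = fit, data = df, fixed_terms = terms_, separation = sep)
}
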