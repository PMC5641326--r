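# Trial-level statistics: one-way ANOVA with Tukey HSD letter groupings, PCA
# on standardized traits, thresholded correlation networks, stepwise yield
# model selection with LMG variance decomposition and the standard error of
# prediction (SEP).

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Factor levels with fewer than 2 observations are excluded with a warning.
#' Pairwise comparisons use Tukey's HSD (Tukey-Kramer on unbalanced designs,
#' as provided by [stats::TukeyHSD()]); two levels share a letter iff their
#' pairwise Tukey p-value is >= `alpha`. When all within-group variance is
#' zero the letters degenerate to grouping by exact mean equality.
#'
#' @param table data.frame.
#' @param trait name of the numeric trait column.
#' @param factor_name name of the grouping factor column.
#' @param alpha significance level (default 0.05).
#' @return list with `means` (data.frame level/mean/n/letters), `anova`
#'   (F statistic, df, p), and `tukey` (pairwise p-value matrix).
#' @export
anova_tukey <- function(table, trait, factor_name, alpha = 0.05) {
  y <- table[[trait]]
  g <- factor(table[[factor_name]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (any(counts < 2)) {
    warning("excluding levels with < 2 observations: ",
            paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
    ok <- g %in% names(counts)[counts >= 2]
    y <- y[ok]; g <- droplevels(g[ok])
  }
  if (nlevels(g) < 2) stop("need >= 2 factor levels with >= 2 observations", call. = FALSE)
  means <- tapply(y, g, mean)
  ns <- as.vector(table(g))
  fit <- aov(y ~ g)
  # the zero-residual case is handled explicitly below; silence the
  # "essentially perfect fit" note anova() emits for it
  atab <- suppressWarnings(anova(fit))
  lv <- levels(g)
  if (atab["Residuals", "Mean Sq"] < 1e-12) {
    # exact separation: no residual variance, groups differ iff means differ
    diffmat <- outer(means, means, function(a, b) abs(a - b) > 1e-12)
    pmat <- ifelse(diffmat, 0, 1)
    diag(pmat) <- NA
    letters <- .compact_letters(lv, diffmat)
    fstat <- Inf; pval <- 0
  } else {
    tk <- TukeyHSD(fit)$g
    pmat <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
    letters <- .compact_letters(lv, pmat < alpha)
    fstat <- atab["g", "F value"]; pval <- atab["g", "Pr(>F)"]
  }
  list(means = data.frame(level = lv, mean = as.vector(means[lv]),
                          n = ns, letters = letters[lv],
                          stringsAsFactors = FALSE),
       anova = list(F = fstat, df = unname(atab$Df), p = pval),
       tukey = pmat)
}

# Insert-and-absorb compact letter display. `different` is a logical matrix:
# TRUE where the pair is significantly different. Guarantees that two levels
# share a letter iff they are NOT significantly different... for the pairwise
# relation itself; letters are assigned greedily in level order.
.compact_letters <- function(lv, different) {
  dimnames(different) <- list(lv, lv)
  cols <- list(lv)  # each column = set of levels sharing one letter
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i || !isTRUE(different[i, j])) next
    a <- lv[i]; b <- lv[j]
    for (k in seq_along(cols)) {
      if (a %in% cols[[k]] && b %in% cols[[k]]) {
        cols[[length(cols) + 1]] <- setdiff(cols[[k]], a)
        cols[[k]] <- setdiff(cols[[k]], b)
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (k in seq_along(cols)) for (m in seq_along(cols)) {
      if (k != m && keep[m] && keep[k] && all(cols[[k]] %in% cols[[m]])) keep[k] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the rank of their first level so "a" is the first group
  first <- vapply(cols, function(s) min(match(s, lv)), numeric(1))
  cols <- cols[order(first)]
  out <- vapply(lv, function(l) {
    paste0(letters[which(vapply(cols, function(s) l %in% s, logical(1)))], collapse = "")
  }, character(1))
  setNames(out, lv)
}

#' Correlation-matrix PCA of trial traits
#'
#' Traits are standardized (correlation-matrix PCA). Constant traits are
#' dropped with a warning. Loadings follow the sign convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param table data.frame of the trial.
#' @param traits character vector of numeric trait columns (>= 2).
#' @return list with `scores`, `loadings` (orthonormal columns),
#'   `explained` (variance shares summing to 1) and `traits` used.
#' @export
pca_traits <- function(table, traits) {
  x <- as.matrix(table[, traits, drop = FALSE])
  if (nrow(x) < 3 || ncol(x) < 2) stop("PCA needs >= 3 rows and >= 2 traits", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant traits: ", paste(traits[sds == 0], collapse = ", "),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2), traits = colnames(x))
}

#' Thresholded Pearson correlation network
#'
#' Computes pairwise Pearson correlations between traits with two-sided
#' p-values from the exact t-transform on n-2 degrees of freedom, and keeps
#' edges with `|r| > r_threshold` and `p < p_threshold` (thresholds applied
#' uncorrected, as is conventional for correlation-network displays). Pairs
#' with fewer than 3 complete observations are skipped.
#'
#' @param table data.frame.
#' @param traits numeric trait columns; default all numeric columns.
#' @param r_threshold,p_threshold edge thresholds (defaults 0.6 and 0.001).
#' @return list with `nodes` and `edges` (data.frame: from, to, r, p, sign).
#' @export
correlation_network <- function(table, traits = NULL, r_threshold = 0.6,
                                p_threshold = 0.001) {
  if (is.null(traits))
    traits <- names(table)[vapply(table, is.numeric, logical(1))]
  edges <- data.frame(from = character(0), to = character(0), r = numeric(0),
                      p = numeric(0), sign = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (j <= i) next
    ct <- cor_test_pearson(table[[traits[i]]], table[[traits[j]]])
    if (is.na(ct$r)) next
    if (abs(ct$r) > r_threshold && ct$p < p_threshold) {
      edges <- rbind(edges, data.frame(
        from = traits[i], to = traits[j], r = ct$r, p = ct$p,
        sign = if (ct$r > 0) "positive" else "negative",
        stringsAsFactors = FALSE))
    }
  }
  list(nodes = traits, edges = edges,
       r_threshold = r_threshold, p_threshold = p_threshold)
}

#' Pearson correlation with exact t-transform p-value
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list with `r`, `p` and `n`; `r = NA` when n < 3 or a vector is
#'   constant.
#' @export
cor_test_pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df = n - 2), n = n)
}

# ---- yield model selection -------------------------------------------------

.fit_r2 <- function(table, response, predictors) {
  f <- if (length(predictors) == 0) paste(response, "~ 1") else
    paste(response, "~", paste(sprintf("`%s`", predictors), collapse = " + "))
  summary(lm(as.formula(f), data = table))$r.squared
}

.fit_lm <- function(table, response, predictors) {
  f <- if (length(predictors) == 0) paste(response, "~ 1") else
    paste(response, "~", paste(sprintf("`%s`", predictors), collapse = " + "))
  lm(as.formula(f), data = table)
}

#' Stepwise selection of a yield prediction model
#'
#' Ordinary least-squares model selection over a candidate set of vegetation
#' indices. With `criterion = "AIC"` the base [stats::step()] search is used;
#' with `criterion = "p"` a classical p-enter/p-remove search. Candidates are
#' sorted lexicographically first so ties break deterministically. With
#' `direction = "both"` forward and backward searches are run separately and
#' any disagreement between the selected sets is reported (not silently
#' resolved); the direction with the lower AIC provides the returned fit.
#'
#' @param table data.frame with the response and candidate columns.
#' @param response response column name (grain yield).
#' @param candidates character vector of candidate predictor names.
#' @param direction "both" (default), "forward" or "backward".
#' @param criterion "AIC" (default) or "p".
#' @param p_enter,p_remove thresholds for the p-value criterion.
#' @return object of class `canopyx_modelfit`: list with `predictors`,
#'   `coefficients`, `intercept`, `r2`, `sep`, `variance_shares`, `n`,
#'   `direction`, `criterion`, `directions` (per-direction selected sets) and
#'   `agree`.
#' @export
stepwise_select <- function(table, response = "gy", candidates,
                            direction = c("both", "forward", "backward"),
                            criterion = c("AIC", "p"),
                            p_enter = 0.05, p_remove = 0.10) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  candidates <- sort(candidates)
  table <- table[complete.cases(table[, c(response, candidates)]), , drop = FALSE]
  if (nrow(table) <= length(candidates) + 1)
    stop("need n > number of candidates + 1", call. = FALSE)
  candidates <- .drop_collinear(table, candidates)
  dirs <- if (direction == "both") c("forward", "backward") else direction
  sets <- lapply(dirs, function(d) {
    if (criterion == "AIC") .step_aic(table, response, candidates, d)
    else .step_p(table, response, candidates, d, p_enter, p_remove)
  })
  names(sets) <- dirs
  agree <- length(sets) == 1 || setequal(sets[[1]], sets[[2]])
  if (!agree)
    warning("forward and backward selections disagree: {",
            paste(sets[[1]], collapse = ","), "} vs {",
            paste(sets[[2]], collapse = ","), "}", call. = FALSE)
  aics <- vapply(sets, function(s) AIC(.fit_lm(table, response, s)), numeric(1))
  chosen <- sets[[which.min(aics)]]
  fit <- .fit_lm(table, response, sort(chosen))
  out <- model_fit_from_lm(fit, table, response)
  out$direction <- direction
  out$criterion <- criterion
  out$directions <- sets
  out$agree <- agree
  out
}

# drop candidates perfectly collinear with earlier ones (QR rank check)
.drop_collinear <- function(table, candidates) {
  keep <- character(0)
  for (cand in candidates) {
    x <- as.matrix(cbind(1, table[, c(keep, cand), drop = FALSE]))
    if (qr(x)$rank == ncol(x)) keep <- c(keep, cand) else
      warning("skipping collinear candidate: ", cand, call. = FALSE)
  }
  keep
}

.step_aic <- function(table, response, candidates, direction) {
  upper <- as.formula(paste("~", paste(sprintf("`%s`", candidates), collapse = " + ")))
  start <- if (direction == "forward") .fit_lm(table, response, character(0))
           else .fit_lm(table, response, candidates)
  sel <- step(start, scope = list(lower = ~1, upper = upper),
              direction = direction, trace = 0)
  setdiff(gsub("`", "", attr(terms(sel), "term.labels")), "")
}

.step_p <- function(table, response, candidates, direction, p_enter, p_remove) {
  current <- if (direction == "forward") character(0) else candidates
  repeat {
    changed <- FALSE
    if (direction == "forward") {
      avail <- setdiff(candidates, current)
      if (length(avail)) {
        ps <- vapply(avail, function(v) .coef_p(table, response, c(current, v), v),
                     numeric(1))
        if (min(ps) < p_enter) { current <- c(current, avail[which.min(ps)]); changed <- TRUE }
      }
    } else {
      if (length(current)) {
        ps <- vapply(current, function(v) .coef_p(table, response, current, v), numeric(1))
        if (max(ps) > p_remove) { current <- setdiff(current, current[which.max(ps)]); changed <- TRUE }
      }
    }
    if (!changed) break
  }
  current
}

.coef_p <- function(table, response, predictors, of) {
  sm <- summary(.fit_lm(table, response, predictors))$coefficients
  row <- paste0("`", of, "`")
  if (!row %in% rownames(sm)) row <- of
  sm[row, "Pr(>|t|)"]
}

#' Build a ModelFit from a fitted lm
#'
#' Packages the coefficients, r-squared, SEP and LMG variance shares of an
#' OLS fit into the common model-fit structure.
#'
#' @param fit an `lm` object.
#' @param table the data it was fitted on.
#' @param response response column name.
#' @return `canopyx_modelfit` list.
#' @export
model_fit_from_lm <- function(fit, table, response) {
  cf <- coef(fit)
  predictors <- gsub("`", "", names(cf)[-1])
  out <- list(predictors = predictors,
              coefficients = setNames(as.vector(cf[-1]), predictors),
              intercept = unname(cf[1]),
              r2 = summary(fit)$r.squared,
              n = length(resid(fit)))
  out$sep <- sep_from_fit(out, table, response)
  out$variance_shares <- if (length(predictors))
    variance_shares(out, table, response) else numeric(0)
  class(out) <- "canopyx_modelfit"
  out
}

#' LMG variance decomposition (relative importance)
#'
#' Each predictor's share of the model R-squared is its incremental
#' R-squared averaged over all orderings of the predictor set (the LMG
#' statistic). Computed exactly by subset enumeration; refuses more than 12
#' predictors unless `sampling = TRUE`, in which case orderings are sampled.
#'
#' @param fit `canopyx_modelfit` (or list with `predictors`).
#' @param table the data.
#' @param response response column name.
#' @param sampling sample 5000 random orderings instead of exact enumeration.
#' @return named vector of shares; shares sum to the model R-squared.
#' @export
variance_shares <- function(fit, table, response, sampling = FALSE) {
  preds <- fit$predictors
  p <- length(preds)
  if (p == 0) return(numeric(0))
  if (p > 12 && !sampling)
    stop("exact LMG enumeration refused for > 12 predictors; set sampling = TRUE",
         call. = FALSE)
  if (sampling && p > 12) {
    shares <- setNames(numeric(p), preds)
    for (s in seq_len(5000)) {
      ord <- sample(preds)
      r2s <- c(0, vapply(seq_len(p), function(k)
        .fit_r2(table, response, ord[seq_len(k)]), numeric(1)))
      shares[ord] <- shares[ord] + diff(r2s)
    }
    return(shares / 5000)
  }
  # exact: share_k = sum over subsets S not containing k of
  #   |S|! (p-|S|-1)! / p!  *  (R2(S+k) - R2(S))
  r2cache <- new.env(parent = emptyenv())
  r2sub <- function(s) {
    key <- paste0(".", paste(sort(s), collapse = "|"))
    if (is.null(r2cache[[key]]))
      r2cache[[key]] <- .fit_r2(table, response, s)
    r2cache[[key]]
  }
  shares <- setNames(numeric(p), preds)
  others <- function(k) setdiff(preds, k)
  for (k in preds) {
    oth <- others(k)
    for (sz in 0:length(oth)) {
      subsets <- if (sz == 0) list(character(0)) else
        combn(oth, sz, simplify = FALSE)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (s in subsets) shares[k] <- shares[k] + w * (r2sub(c(s, k)) - r2sub(s))
    }
  }
  shares
}

#' Standard error of prediction of a fitted model
#'
#' SEP is taken as the residual standard error,
#' sqrt(RSS / (n - p - 1)); undefined (NA with warning) when n <= p + 1.
#'
#' @inheritParams variance_shares
#' @return SEP (response units).
#' @export
sep_from_fit <- function(fit, table, response) {
  lmfit <- .fit_lm(table, response, fit$predictors)
  n <- length(resid(lmfit)); p <- length(fit$predictors)
  if (n <= p + 1) { warning("SEP undefined: n <= p + 1", call. = FALSE); return(NA_real_) }
  sqrt(sum(resid(lmfit)^2) / (n - p - 1))
}

#' Apply a linear yield model to new rows
#'
#' @param coefficients named vector of predictor coefficients.
#' @param intercept model intercept.
#' @param row data.frame (or named list) with all predictor columns.
#' @return predicted response, one value per row.
#' @export
apply_model <- function(coefficients, intercept, row) {
  missing <- setdiff(names(coefficients), names(row))
  if (length(missing))
    stop("missing predictors: ", paste(missing, collapse = ", "), call. = FALSE)
  vals <- vapply(names(coefficients),
                 function(nm) as.numeric(row[[nm]]),
                 numeric(length(row[[names(coefficients)[1]]])))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  as.vector(intercept + vals %*% coefficients)
}

#' Published yield-model fixtures
#'
#' The three printed multivariate yield models (aerial, ground and combined
#' VI sets) with their coefficients, r-squared, SEP and per-predictor
#' variance shares, shipped as a fixture for prediction and bookkeeping.
#'
#' @return named list of model definitions.
#' @export
yield_model_fixtures <- function() {
  jsonlite::read_json(system.file("extdata", "table4_models.json", package = "canopyx"),
                      simplifyVector = TRUE)
}

#' Two-way ANOVA with interaction
#'
#' Genotype x treatment ANOVA for one trait; main effects are the default
#' display of trial summaries, but the interaction term is always computed
#' and reported.
#'
#' @param table trial data.frame with `genotype` and `treatment` columns.
#' @param trait numeric trait column name.
#' @return the `anova` table of the `lm` fit with interaction.
#' @export
anova_interaction <- function(table, trait) {
  f <- as.formula(paste(sprintf("`%s`", trait), "~ genotype * treatment"))
  anova(lm(f, data = table))
}
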