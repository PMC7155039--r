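# Attribution of surface-water trends to climate and human water use:
# regression random forest (bootstrap trees, random per-split predictor
# subsetting), Breiman-Cutler permutation variable importance over
# out-of-bag rows, and double-bootstrap-style subsampling confidence
# intervals for the importances.

EW_PREDICTORS <- c("ET", "PR", "RO", "SWE", "irrigated_frac", "density_km2")

#' Assemble the watershed-year model table
#'
#' Inner-joins the annual water-area response for one class with the
#' water-year climate summaries and the human-use series. Rows with any
#' missing field (the 2012 gap in particular) are dropped with a message;
#' monsoonal tables end at 2017 (climate coverage rule).
#'
#' @param water `water` data.frame from [build_series()]
#' @param climate data.frame with `year`, `ET`, `PR`, `RO`, `SWE` (mm,
#'   already summarized on the regional water year: Oct-Sep for snowmelt,
#'   Apr-Mar for monsoonal watersheds)
#' @param human `human` data.frame from [build_series()]
#' @param region "snowmelt" or "monsoonal"
#' @param class response class (default "lake")
#' @return a `model_table` data.frame: watershed, year, area_ha and the
#'   six predictors
#' @export
assemble_design <- function(water, climate, human,
                            region = c("snowmelt", "monsoonal"),
                            class = "lake") {
  region <- match.arg(region)
  w <- water[water$class == class, c("watershed", "year", "area_ha")]
  if (nrow(w) == 0) stop("no rows for class '", class, "'")
  if (!all(human$watershed %in% w$watershed))
    stop("mismatched watershed ids between water and human series")
  tb <- merge(w, climate, by = "year")
  tb <- merge(tb, human[, c("watershed", "year", "irrigated_frac",
                            "density_km2")],
              by = c("watershed", "year"))
  if (nrow(tb) == 0) stop("empty join between water, climate and human series")
  if (region == "monsoonal") tb <- tb[tb$year <= 2017, ]
  keep <- stats::complete.cases(tb[, c("area_ha", EW_PREDICTORS)])
  if (any(!keep))
    message(sum(!keep), " watershed-year row(s) dropped for missing values")
  tb <- tb[keep, c("watershed", "year", "area_ha", EW_PREDICTORS)]
  tb <- tb[order(tb$watershed, tb$year), ]
  rownames(tb) <- NULL
  attr(tb, "region") <- region
  attr(tb, "response_class") <- class
  class(tb) <- c("model_table", "data.frame")
  tb
}

#' Model table straight from bundle truth
#'
#' Assembles the watershed-year design from a synthetic bundle's truth
#' area tables (bypassing the imaging pipeline), for attribution
#' experiments where the imaging stages are not under test.
#'
#' @param bundle a `watershed_bundle`
#' @param class response class (default "wetland")
#' @return a `model_table`
#' @export
truth_design <- function(bundle, class = "wetland") {
  human <- merge(bundle$human_truth, bundle$population, by = "year")
  human$watershed <- bundle$params$watershed
  assemble_design(bundle$truth_areas, bundle$climate, human,
                  region = bundle$params$regime, class = class)
}

table_xy <- function(table, predictors) {
  X <- as.matrix(table[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(table$area_ha))
}

#' Fit a regression random forest
#'
#' Each tree is grown on a bootstrap resample with `mtry` randomly chosen
#' candidate predictors per split and terminal nodes of at least
#' `min_node` rows; out-of-bag predictions are retained for error and
#' importance estimation. Identical seeds give identical forests.
#'
#' @param table a `model_table` (or data.frame with `area_ha` and
#'   predictor columns)
#' @param n_trees number of trees (default 5000, the headline model size)
#' @param mtry candidate predictors per split, default `ceiling(p/3)`
#' @param min_node minimum node size to attempt a split (default 5)
#' @param predictors predictor column names
#' @param seed integer seed (required for reproducibility)
#' @param replace bootstrap (TRUE) or subsample without replacement
#' @param sampsize rows drawn per tree (default n)
#' @return an `ew_forest`: trees, inbag matrix, OOB predictions, OOB
#'   mean-squared error and R^2
#' @export
fit_forest <- function(table, n_trees = 5000, mtry = NULL, min_node = 5,
                       predictors = intersect(EW_PREDICTORS, names(table)),
                       seed = 1, replace = TRUE, sampsize = NULL) {
  d <- table_xy(table, predictors)
  n <- nrow(d$X); p <- ncol(d$X)
  stopifnot(n >= 10, p >= 2)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  if (is.null(sampsize)) sampsize <- n
  set.seed(seed)
  fit <- .rf_fit_cpp(d$X, d$y, as.integer(n_trees), as.integer(mtry),
                     as.integer(min_node), replace, as.integer(sampsize))
  oob <- drop(fit$oob_pred)
  ok <- is.finite(oob)
  mse <- mean((d$y[ok] - oob[ok])^2)
  vy <- var(d$y)
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 oob_pred = oob, oob_mse = mse,
                 oob_r2 = if (vy > 0) 1 - mse / vy else NA_real_,
                 predictors = predictors, X = d$X, y = d$y,
                 n_trees = n_trees, mtry = mtry, min_node = min_node,
                 seed = seed),
            class = "ew_forest")
}

#' @export
print.ew_forest <- function(x, ...) {
  cat(sprintf("<ew_forest> %d trees, mtry %d, n=%d, OOB R^2 %.3f\n",
              x$n_trees, x$mtry, length(x$y), x$oob_r2))
  invisible(x)
}

#' Predict from a fitted forest
#' @param object an `ew_forest`
#' @param newdata data.frame holding the predictor columns
#' @param ... unused
#' @export
predict.ew_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  drop(.rf_predict_cpp(object$trees, X))
}

#' Breiman-Cutler permutation variable importance
#'
#' For each tree and predictor, the increase in out-of-bag mean squared
#' error after permuting that predictor over the tree's OOB rows, averaged
#' across trees. A predictor independent of the response has importance
#' near zero (within about two tree-level standard errors).
#'
#' @param forest an `ew_forest`
#' @param seed integer seed for the permutations (default: forest seed + 1)
#' @return a `vimp_result` data.frame: predictor, vimp, se_trees, rank
#' @export
permutation_vimp <- function(forest, seed = forest$seed + 1L) {
  set.seed(seed)
  r <- .rf_vimp_cpp(forest$trees, forest$inbag, forest$X, forest$y)
  out <- data.frame(predictor = forest$predictors,
                    vimp = drop(r$vimp), se_trees = drop(r$se))
  out$rank <- rank(-out$vimp, ties.method = "first")
  class(out) <- c("vimp_result", "data.frame")
  out
}

#' Subsampling confidence intervals for permutation importance
#'
#' Double-bootstrap-style intervals: the point estimate comes from a
#' full-data forest; B subsamples without replacement of size
#' `ceiling(n^0.8)` each refit a reduced forest and recompute VIMP, and the
#' CI is the normal interval with the subsampling variance rescaled by
#' m/n to full-sample size.
#'
#' @param table a `model_table`
#' @param B number of subsamples (default 500; fewer than 50 draws a
#'   warning but is computed)
#' @param alpha two-sided level (default 0.05)
#' @param seed integer seed
#' @param n_trees trees for the full-data point estimate
#' @param n_trees_sub trees per subsample forest (reduced for cost)
#' @param subsample_exponent m = ceiling(n^exponent), default 0.8
#' @param ... passed to [fit_forest()]
#' @return a `vimp_result` with `lower`/`upper` columns
#' @export
vimp_confidence <- function(table, B = 500, alpha = 0.05, seed = 1,
                            n_trees = 1000, n_trees_sub = 500,
                            subsample_exponent = 0.8, ...) {
  stopifnot(nrow(table) >= 20)
  if (B < 50) warning("B < 50 subsamples gives unstable intervals")
  full <- fit_forest(table, n_trees = n_trees, seed = seed, ...)
  point <- permutation_vimp(full)
  n <- nrow(table)
  m <- ceiling(n^subsample_exponent)
  p <- length(full$predictors)
  vb <- matrix(NA_real_, B, p)
  set.seed(seed + 1L)
  subseeds <- sample.int(2^30, B)
  for (b in seq_len(B)) {
    set.seed(subseeds[b])
    rows <- sample.int(n, m, replace = FALSE)
    fb <- fit_forest(table[rows, , drop = FALSE], n_trees = n_trees_sub,
                     seed = subseeds[b] + 1L, ...)
    vb[b, ] <- permutation_vimp(fb)$vimp
  }
  # rescale subsampling variance from size m to size n
  v <- apply(vb, 2, var) * m / n
  z <- qnorm(1 - alpha / 2)
  point$lower <- point$vimp - z * sqrt(v)
  point$upper <- point$vimp + z * sqrt(v)
  attr(point, "B") <- B
  attr(point, "subsample_size") <- m
  point
}

#' Rank predictors and summarize importance across watersheds
#'
#' Orders predictors by point importance. With several watershed results,
#' importances are first standardized within each result (divided by the
#' maximum importance, the convention used for cross-panel comparison) and
#' the 5/25/50/75/95 percentile summaries of the standardized scores are
#' reported per predictor, boxplot-style.
#'
#' @param results a `vimp_result` or list of them (one per watershed)
#' @return data.frame: predictor, median standardized vimp, quartiles and
#'   whiskers, mean rank, and overall rank
#' @export
rank_predictors <- function(results) {
  if (inherits(results, "vimp_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  preds <- results[[1]]$predictor
  std <- sapply(results, function(r) {
    stopifnot(identical(r$predictor, preds))
    r$vimp / max(r$vimp)
  })
  std <- matrix(std, nrow = length(preds))
  ranks <- sapply(results, function(r) r$rank)
  ranks <- matrix(ranks, nrow = length(preds))
  qs <- t(apply(std, 1, quantile, c(0.05, 0.25, 0.5, 0.75, 0.95),
                names = FALSE))
  out <- data.frame(predictor = preds,
                    q05 = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                    q75 = qs[, 4], q95 = qs[, 5],
                    mean_rank = rowMeans(ranks))
  out <- out[order(-out$median), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
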