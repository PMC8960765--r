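# Date- and tile-specific downscaling: a rule-based regression tree (M5
# style model tree: variance-reduction splits, a linear model in each leaf,
# bottom-up pruning against the leaf models, leaves linearized into ordered
# rules) is trained on 30 m (fine-sensor VI, reference LAI) pairs and then
# applied to the 7 fine-sensor indices at 3 m. Training strictly at 30 m,
# prediction strictly at 3 m.

#' Downscaler hyperparameters
#'
#' `min_leaf`: minimum rows per leaf; `max_depth`: maximum tree depth;
#' `ridge`: penalty used only when a leaf design is ill-conditioned;
#' `n_split_quantiles`: candidate thresholds per predictor (quantile grid);
#' `sd_stop`: stop splitting when a node's target spread falls below this
#' fraction of the global spread; `lai_max`: prediction clip ceiling.
#'
#' @return named list of settings.
#' @export
downscaler_defaults <- function() {
  list(min_leaf = 50, max_depth = 6, ridge = 1e-3, n_split_quantiles = 32,
       sd_stop = 0.05, lai_max = 8)
}

#' Full-tile training budget
#'
#' The downscaler trains on the 30 m grid, so a full fine-sensor tile
#' contributes one training sample per whole 30 m cell: a tile of
#' `n_rows x n_cols` 3 m pixels yields `(n_rows/10) * (n_cols/10)` samples
#' (an 8000 x 8000 tile gives 640,000).
#'
#' @param n_rows,n_cols fine-grid tile dimensions in pixels.
#' @param factor fine-to-coarse aggregation factor (default 10).
#' @return number of training samples.
#' @export
training_budget <- function(n_rows, n_cols, factor = 10L) {
  (n_rows %/% factor) * (n_cols %/% factor)
}

#' Sample 30 m training pixels
#'
#' Pairs the reference-tile LAI with the 30 m fine-sensor VI stack and draws
#' a reproducible subsample of valid pixels.
#'
#' @param reference_tile a [build_reference_tile()] result (or a 30 m LAI
#'   [sat_raster]).
#' @param vi_stack_30m 30 m [sat_raster] of the 7 shared indices.
#' @param fraction_or_count fraction (<= 1) or count of valid pixels to keep.
#' @param seed integer seed.
#' @return data frame: one VI column per index, `lai`, `weight`.
#' @export
sample_training_pixels <- function(reference_tile, vi_stack_30m,
                                   fraction_or_count = 1, seed = 1) {
  lai_r <- if (inherits(reference_tile, "reference_tile")) reference_tile$lai else reference_tile
  w_r <- if (inherits(reference_tile, "reference_tile")) reference_tile$weight else NULL
  if (!identical(dim(lai_r$values)[1:2], dim(vi_stack_30m$values)[1:2]))
    stopf("reference and VI grids differ")
  d <- dim(vi_stack_30m$values)
  X <- matrix(vi_stack_30m$values, d[1] * d[2], d[3],
              dimnames = list(NULL, vi_stack_30m$bands))
  y <- as.vector(raster_band(lai_r, 1L))
  w <- if (is.null(w_r)) rep(1, length(y)) else as.vector(raster_band(w_r, 1L))
  ok <- which(stats::complete.cases(X) & is.finite(y))
  if (!length(ok)) stopf("no valid training pixels")
  n <- if (fraction_or_count <= 1) max(1L, round(fraction_or_count * length(ok)))
       else as.integer(fraction_or_count)
  if (n > length(ok))
    stopf("requested %d training pixels but only %d are valid", n, length(ok))
  sel <- if (n == length(ok)) ok else with_seed(seed, sample(ok, n))
  out <- as.data.frame(X[sel, , drop = FALSE])
  out$lai <- y[sel]
  out$weight <- w[sel]
  out
}

# Leaf linear model: OLS via QR; ridge only when the design is
# rank-deficient or ill-conditioned, keeping exact fits exact.
fit_leaf_lm <- function(X, y, ridge) {
  D <- cbind(1, X)
  fit <- stats::lm.fit(D, y)
  co <- fit$coefficients
  ill <- anyNA(co)
  if (!ill) {
    R <- qr.R(fit$qr)
    dg <- abs(diag(R))
    ill <- min(dg) <= 1e-10 * max(dg)
  }
  if (ill) {
    A <- crossprod(D) + diag(c(0, rep(ridge, ncol(X))))
    co <- drop(solve(A, crossprod(D, y)))
  }
  co[is.na(co)] <- 0
  names(co) <- c("(Intercept)", colnames(X))
  co
}

leaf_rss <- function(co, X, y) sum((y - drop(cbind(1, X) %*% co))^2)

# Best variance-reduction split over a quantile grid of candidate thresholds.
best_split <- function(X, y, min_leaf, n_q) {
  n <- length(y)
  best <- NULL; base <- sum((y - mean(y))^2)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    qs <- unique(stats::quantile(xj, probs = seq_len(n_q) / (n_q + 1), type = 7))
    for (t in qs) {
      left <- xj < t
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      yl <- y[left]; yr <- y[!left]
      sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      if (is.null(best) || sse < best$sse)
        best <- list(var = j, threshold = t, sse = sse)
    }
  }
  if (!is.null(best) && best$sse >= base) best <- NULL
  best
}

grow_tree <- function(X, y, depth, hp, sd_global) {
  node <- list(n = length(y))
  stop_here <- length(y) < 2L * hp$min_leaf || depth >= hp$max_depth ||
    stats::sd(y) < hp$sd_stop * sd_global
  sp <- if (stop_here) NULL else best_split(X, y, hp$min_leaf, hp$n_split_quantiles)
  node$coef <- fit_leaf_lm(X, y, hp$ridge)
  node$rss <- leaf_rss(node$coef, X, y)
  if (is.null(sp)) { node$leaf <- TRUE; return(node) }
  left <- X[, sp$var] < sp$threshold
  node$leaf <- FALSE
  node$var <- colnames(X)[sp$var]; node$threshold <- sp$threshold
  node$left <- grow_tree(X[left, , drop = FALSE], y[left], depth + 1L, hp, sd_global)
  node$right <- grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L, hp, sd_global)
  # M5 pruning: keep the subtree only if it beats this node's own linear
  # model after a light complexity adjustment.
  sub_rss <- subtree_rss(node)
  k <- n_leaves(node)
  penalty <- (node$n + 2 * k) / max(node$n - 2 * k, 1)
  tss <- sum((y - mean(y))^2)
  if (node$rss <= sub_rss * penalty + 1e-12 * max(tss, 1)) {
    node <- list(n = node$n, coef = node$coef, rss = node$rss, leaf = TRUE)
  }
  node
}

subtree_rss <- function(node) {
  if (node$leaf) node$rss else subtree_rss(node$left) + subtree_rss(node$right)
}
n_leaves <- function(node) {
  if (node$leaf) 1L else n_leaves(node$left) + n_leaves(node$right)
}

# Depth-first linearization of leaves into ordered rules; conditions are
# half-open (var < t on the left branch, var >= t on the right).
tree_rules <- function(node, conds = list()) {
  if (node$leaf)
    return(list(list(conds = conds, coef = node$coef, n = node$n)))
  c(tree_rules(node$left, c(conds, list(list(var = node$var, op = "<", threshold = node$threshold)))),
    tree_rules(node$right, c(conds, list(list(var = node$var, op = ">=", threshold = node$threshold)))))
}

#' Train the date/tile-specific rule model
#'
#' Grows an M5-style model tree on the sampled 30 m design, prunes it
#' against per-node linear models and linearizes the leaves into ordered
#' rules. A degenerate design (constant predictors) collapses to the global
#' linear model, flagged.
#'
#' @param design data frame from [sample_training_pixels()] (VI columns +
#'   `lai`, optional `weight`).
#' @param hyperparams see [downscaler_defaults()].
#' @param seed recorded for provenance (training itself is deterministic).
#' @param date,tile optional tags naming the day/tile this model belongs to.
#' @return object of class `rule_model`.
#' @export
train_rule_model <- function(design, hyperparams = downscaler_defaults(),
                             seed = 1, date = NULL, tile = NULL) {
  hp <- utils::modifyList(downscaler_defaults(), hyperparams)
  feats <- setdiff(colnames(design), c("lai", "weight"))
  if (!length(feats)) stopf("design has no predictor columns")
  if (nrow(design) < 2L) stopf("design has fewer than 2 rows")
  X <- as.matrix(design[, feats, drop = FALSE])
  y <- design$lai
  fallback <- fit_leaf_lm(X, y, hp$ridge)
  degenerate <- all(apply(X, 2L, function(v) diff(range(v)) == 0))
  if (degenerate) {
    rules <- list(list(conds = list(), coef = fallback, n = nrow(X)))
    warnf("constant predictors: falling back to a single global linear model")
  } else {
    tree <- grow_tree(X, y, 0L, hp, stats::sd(y))
    rules <- tree_rules(tree)
  }
  model <- structure(list(rules = rules, fallback = fallback, features = feats,
                          lai_max = hp$lai_max, date = date, tile = tile,
                          seed = seed, n_train = nrow(X),
                          degenerate = degenerate),
                     class = "rule_model")
  pred <- predict(model, X, clip = FALSE)
  model$r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  model
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("<rule_model> %d rule(s) on %d predictors, %d training rows, R2 = %.4f\n",
              length(x$rules), length(x$features), x$n_train, x$r2))
  if (!is.null(x$date)) cat("  date:", format(x$date),
                            if (!is.null(x$tile)) paste(" tile:", x$tile), "\n")
  for (i in seq_len(min(4L, length(x$rules)))) {
    r <- x$rules[[i]]
    cond <- if (length(r$conds)) paste(vapply(r$conds, function(cn)
      sprintf("%s %s %.3g", cn$var, cn$op, cn$threshold), ""), collapse = " & ")
      else "TRUE"
    cat(sprintf("  [%d] %s  (n=%d)\n", i, cond, r$n))
  }
  if (length(x$rules) > 4L) cat(sprintf("  ... %d more rule(s)\n", length(x$rules) - 4L))
  invisible(x)
}

#' Predict LAI from a rule model
#'
#' Each pixel is routed to the first rule whose conditions it satisfies
#' (rules partition the predictor space; the global fallback model covers
#' any residual case), evaluated with that rule's linear model, and clipped
#' to `[0, lai_max]`. Missing predictors propagate as `NA`.
#'
#' @param object a `rule_model`.
#' @param newdata [sat_raster] VI stack (any resolution) or a numeric matrix
#'   with the training predictors as columns.
#' @param clip clip predictions to `[0, lai_max]` (default TRUE).
#' @param ... unused.
#' @return [sat_raster] of LAI for raster input, numeric vector otherwise.
#' @export
predict.rule_model <- function(object, newdata, clip = TRUE, ...) {
  as_matrix <- is.matrix(newdata)
  if (!as_matrix) {
    d <- dim(newdata$values)
    X <- matrix(newdata$values, d[1] * d[2], d[3],
                dimnames = list(NULL, newdata$bands))
  } else X <- newdata
  miss <- setdiff(object$features, colnames(X))
  if (length(miss)) stopf("predictors missing from input: %s",
                          paste(miss, collapse = ", "))
  X <- X[, object$features, drop = FALSE]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  unassigned <- ok
  for (r in object$rules) {
    m <- unassigned
    for (cn in r$conds) {
      v <- X[, cn$var]
      m <- m & if (cn$op == "<") v < cn$threshold else v >= cn$threshold
      m[is.na(m)] <- FALSE
    }
    if (any(m)) {
      out[m] <- drop(cbind(1, X[m, , drop = FALSE]) %*% r$coef)
      unassigned <- unassigned & !m
    }
  }
  if (any(unassigned))
    out[unassigned] <- drop(cbind(1, X[unassigned, , drop = FALSE]) %*% object$fallback)
  if (clip) out <- pmin(pmax(out, 0), object$lai_max)
  if (as_matrix) return(out)
  sat_raster(array(out, c(d[1], d[2], 1L)), "lai", newdata$res, newdata$origin,
             newdata$date, kind = "lai", nodata = newdata$nodata)
}
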