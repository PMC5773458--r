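# Weighted GA-MLR 3D-QSAR: model container, Table-2 presets, prediction,
# weighted least squares, leave-one-out Q2, genetic-algorithm feature
# selection, validation and contribution decomposition.

#' Construct a QSAR model
#'
#' A linear model \eqn{pIC_{50} = \sum_i c_i FP_i + C} over an ordered subset
#' of the fingerprint features, with a per-class weighting policy used
#' during fitting (Type I steroids carry full weight; Type II
#' azaheterocycles are down-weighted because their binding mode is less
#' certain).
#'
#' @param features character vector, subset of \code{FP1..FP9}.
#' @param coefficients named numeric vector of \eqn{c_i} (log units per unit
#'   descriptor), names matching \code{features}.
#' @param intercept the constant C (log units).
#' @param weights_policy named vector of per-class weights.
#' @param provenance \code{"fitted"}, \code{"table2_steroid"} or
#'   \code{"table2_generalized"}.
#' @return object of class \code{qsar_model}.
#' @export
qsar_model <- function(features, coefficients, intercept,
                       weights_policy = c(steroid = 1.0, azaheterocycle = 0.1),
                       provenance = "fitted") {
  stopifnot(is.character(features), length(features) >= 1,
            setequal(names(coefficients), features),
            is.numeric(intercept), length(intercept) == 1)
  structure(list(features = features,
                 coefficients = coefficients[features],
                 intercept = unname(intercept),
                 weights_policy = weights_policy,
                 provenance = provenance),
            class = "qsar_model")
}

#' Published model presets
#'
#' Two fixed coefficient sets: the steroid-only model (no FP5/FP6/FP8) and
#' the generalized model covering both inhibitor classes.  In the
#' generalized model the FP8 column holds the already-transformed
#' coordination term (\code{\link{fp8_term}}), so its coefficient is 1.
#'
#' @param name \code{"table2_generalized"} or \code{"table2_steroid"}.
#' @return a \code{qsar_model}.
#' @export
qsar_preset <- function(name = c("table2_generalized", "table2_steroid")) {
  name <- match.arg(name)
  if (name == "table2_generalized") {
    qsar_model(
      features = paste0("FP", 1:9),
      coefficients = c(FP1 = 0.229, FP2 = 0.621, FP3 = 0.710, FP4 = 0.821,
                       FP5 = 1.278, FP6 = 2.237, FP7 = 0.724, FP8 = 1.0,
                       FP9 = 1.969),
      intercept = 0.755, provenance = name
    )
  } else {
    qsar_model(
      features = c("FP1", "FP2", "FP3", "FP4", "FP7", "FP9"),
      coefficients = c(FP1 = 0.296, FP2 = 0.679, FP3 = 0.791, FP4 = 0.823,
                       FP7 = 0.721, FP9 = 2.234),
      intercept = 0.270, provenance = name
    )
  }
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model [%s]: %d features, intercept %.3f>\n",
              x$provenance, length(x$features), x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Coerce a fingerprint (named vector, interaction_fingerprint, list, or
# data.frame of rows) to a numeric matrix with the model's feature columns.
fp_matrix <- function(fp, features) {
  if (is.data.frame(fp)) {
    missing <- setdiff(features, names(fp))
    if (length(missing))
      stop("fingerprint missing selected feature(s): ", paste(missing, collapse = ", "))
    return(as.matrix(fp[, features, drop = FALSE]))
  }
  v <- unlist(fp)
  missing <- setdiff(features, names(v))
  if (length(missing))
    stop("fingerprint missing selected feature(s): ", paste(missing, collapse = ", "))
  matrix(v[features], nrow = 1, dimnames = list(NULL, features))
}

#' Predict pIC50 from a fingerprint
#'
#' \eqn{pIC_{50} = \sum_i c_i FP_i + C} over the model's selected features.
#'
#' @param model a \code{qsar_model}.
#' @param fp a named fingerprint vector (\code{FP1..FP9}) or a data.frame of
#'   fingerprint rows.
#' @return numeric prediction(s).
#' @export
predict_pic50 <- function(model, fp) {
  x <- fp_matrix(fp, model$features)
  as.numeric(x %*% model$coefficients + model$intercept)
}

#' @export
predict.qsar_model <- function(object, newdata, ...) {
  predict_pic50(object, newdata)
}

#' Fold change in inhibition potency implied by a coefficient
#'
#' A binary feature with coefficient \eqn{c_i} multiplies IC50 by
#' \eqn{10^{-c_i}}, i.e. improves potency \eqn{10^{c_i}}-fold.  Reported at
#' the conventional precision: two significant figures below 10, nearest
#' integer above.
#'
#' @param c_i regression coefficient (log units).
#' @return the fold change.
#' @export
fold_change <- function(c_i) {
  fc <- 10^c_i
  ifelse(fc < 10, signif(fc, 2), round(fc))
}

# --- weighted least squares -------------------------------------------------

# Design matrix with intercept column first.
design_matrix <- function(x, features = colnames(x)) {
  x <- as.matrix(x[, features, drop = FALSE])
  cbind(`(Intercept)` = 1, x)
}

#' Fit a weighted multiple linear regression
#'
#' Exact weighted least squares minimising \eqn{\sum_i w_i (y_i -
#' \hat y_i)^2} via the normal equations (QR-solved).  A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param x numeric matrix or data.frame of descriptor columns.
#' @param y response vector (pIC50).
#' @param weights per-sample weights (> 0); default all 1 (ordinary least
#'   squares).
#' @param weights_policy stored on the returned model for later refits.
#' @return a \code{qsar_model} with \code{provenance = "fitted"}; attribute
#'   \code{fit} carries residuals, fitted values and leverages.
#' @export
fit_weighted_mlr <- function(x, y, weights = NULL,
                             weights_policy = c(steroid = 1.0, azaheterocycle = 0.1)) {
  x <- as.data.frame(x)
  feats <- colnames(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  if (n <= length(feats) + 1)
    stop("need more samples than features plus intercept")
  X <- design_matrix(x, feats)
  sw <- sqrt(weights)
  qrX <- qr(X * sw)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y * sw)
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  # leverages of the weighted fit: h_i = w_i x_i' (X'WX)^{-1} x_i
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  model <- qsar_model(features = feats,
                      coefficients = stats::setNames(beta[-1], feats),
                      intercept = beta[1],
                      weights_policy = weights_policy,
                      provenance = "fitted")
  attr(model, "fit") <- list(fitted = fitted, residuals = resid,
                             leverage = h, weights = weights, y = y)
  model
}

# Weighted mean / Pearson helpers.
wmean <- function(x, w) sum(w * x) / sum(w)
wpearson2 <- function(x, y, w) {
  mx <- wmean(x, w); my <- wmean(y, w)
  cxy <- sum(w * (x - mx) * (y - my))
  cxy^2 / (sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

#' Leave-one-out cross-validated Q2 for weighted least squares
#'
#' Each sample is predicted from a refit on the remaining samples (with
#' their weights); \eqn{Q^2 = 1 - \sum w_i e_{(-i)}^2 / \sum w_i (y_i -
#' \bar y_w)^2}.  The default \code{"shortcut"} method uses the exact
#' hat-matrix identity \eqn{e_{(-i)} = e_i / (1 - h_{ii})}; the
#' \code{"refit"} method performs the n explicit refits and exists as the
#' oracle cross-check.
#'
#' @param x descriptor matrix/data.frame.
#' @param y response vector.
#' @param weights per-sample weights (default all 1).
#' @param method \code{"shortcut"} or \code{"refit"}.
#' @return list with \code{q2}, \code{press} (weighted PRESS) and
#'   \code{e_loo} (deleted residuals).
#' @export
loo_q2 <- function(x, y, weights = NULL, method = c("shortcut", "refit")) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (method == "shortcut") {
    model <- fit_weighted_mlr(x, y, weights)
    f <- attr(model, "fit")
    e_loo <- f$residuals / (1 - f$leverage)
  } else {
    e_loo <- vapply(seq_len(n), function(i) {
      m <- fit_weighted_mlr(x[-i, , drop = FALSE], y[-i], weights[-i])
      y[i] - predict_pic50(m, x[i, , drop = FALSE])
    }, numeric(1))
  }
  press <- sum(weights * e_loo^2)
  sst <- sum(weights * (y - wmean(y, weights))^2)
  list(q2 = 1 - press / sst, press = press, e_loo = e_loo)
}

# --- genetic algorithm ------------------------------------------------------

#' Genetic-algorithm configuration
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param mutation_rate per-bit mutation probability.
#' @param elitism number of best individuals copied unchanged.
#' @param parsimony per-feature fitness penalty.  A noise feature improves
#'   leave-one-out Q2 whenever its spurious t-statistic exceeds about 1,
#'   which is frequent at any sample size, so subset selection on raw Q2
#'   alone retains junk; the small penalty makes a feature earn its place.
#' @param seed RNG seed (the search is deterministic given the seed).
#' @return list of class \code{ga_config}.
#' @export
ga_config <- function(pop_size = 50, generations = 100, mutation_rate = 0.02,
                      elitism = 2, parsimony = 0.002, seed = 1) {
  structure(list(pop_size = pop_size, generations = generations,
                 mutation_rate = mutation_rate, elitism = elitism,
                 parsimony = parsimony, seed = seed), class = "ga_config")
}

#' Genetic-algorithm feature selection for the weighted MLR
#'
#' Binary-mask GA over the candidate feature pool maximising the
#' parsimony-penalised leave-one-out \eqn{Q^2} of the weighted fit
#' (tournament selection,
#' uniform crossover, bit-flip mutation, elitism).  The returned subset is
#' the best mask ever seen; its fitness is not guaranteed to dominate the
#' full feature set, so both are reported.
#'
#' @param x descriptor matrix/data.frame over the candidate pool.
#' @param y response vector.
#' @param weights per-sample weights.
#' @param config a \code{\link{ga_config}}.
#' @return list with \code{selected} (feature names), \code{model} (refit on
#'   the subset), \code{fitness} (its Q2), and \code{full_fitness} (Q2 of
#'   the full pool).
#' @export
ga_select <- function(x, y, weights = NULL, config = ga_config()) {
  x <- as.data.frame(x)
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  fitness_of <- function(mask) {
    if (!any(mask)) return(-Inf)
    q2 <- tryCatch(
      loo_q2(x[, mask, drop = FALSE], y, weights)$q2,
      error = function(e) -Inf
    )
    q2 - config$parsimony * sum(mask)
  }
  full_fit <- fitness_of(rep(TRUE, p))
  if (p == 1) {
    model <- fit_weighted_mlr(x, y, weights)
    return(list(selected = feats, model = model, fitness = full_fit,
                full_fitness = full_fit))
  }
  with_seed(config$seed, {
    popn <- matrix(stats::runif(config$pop_size * p) < 0.5, config$pop_size, p)
    popn[1, ] <- TRUE  # seed the full model into the population
    fits <- apply(popn, 1, fitness_of)
    best_mask <- popn[which.max(fits), ]
    best_fit <- max(fits)
    for (g in seq_len(config$generations)) {
      ord <- order(fits, decreasing = TRUE)
      new_pop <- popn[ord[seq_len(config$elitism)], , drop = FALSE]
      while (nrow(new_pop) < config$pop_size) {
        # tournament selection of two parents
        pick <- function() {
          cand <- sample.int(config$pop_size, 2)
          cand[which.max(fits[cand])]
        }
        pa <- popn[pick(), ]; pb <- popn[pick(), ]
        cross <- stats::runif(p) < 0.5
        child <- ifelse(cross, pa, pb)
        flip <- stats::runif(p) < config$mutation_rate
        child[flip] <- !child[flip]
        new_pop <- rbind(new_pop, child)
      }
      popn <- new_pop
      fits <- apply(popn, 1, fitness_of)
      if (max(fits) > best_fit) {
        best_fit <- max(fits)
        best_mask <- popn[which.max(fits), ]
      }
    }
    model <- fit_weighted_mlr(x[, best_mask, drop = FALSE], y, weights)
    list(selected = feats[best_mask], model = model, fitness = best_fit,
         full_fitness = full_fit)
  })
}

# --- validation -------------------------------------------------------------

#' Train/test validation of the weighted QSAR
#'
#' Stratified random split by inhibitor class, weighted fit on the training
#' set, and a Table-3-style report: training \eqn{R^2} (squared Pearson
#' correlation, the common QSAR convention) and coefficient of
#' determination, leave-one-out \eqn{Q^2} (weighted, matching the fitting
#' weights), MAE, and external-set metrics, each overall and per class.
#' Overall training R2/Q2 are weighted (the fit is); per-class rows are
#' plain unweighted metrics.
#'
#' @param x descriptor matrix/data.frame.
#' @param y response vector.
#' @param classes character vector (\code{"steroid"} /
#'   \code{"azaheterocycle"}) per sample.
#' @param weights_policy named per-class weight vector.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.7); \code{1} is the degenerate spec where the external set
#'   equals the training set.
#' @param seed split seed.
#' @return list of class \code{fit_report}.
#' @export
validate_qsar <- function(x, y, classes,
                          weights_policy = c(steroid = 1.0, azaheterocycle = 0.1),
                          train_fraction = 0.7, seed = 1) {
  x <- as.data.frame(x)
  n <- nrow(x)
  stopifnot(length(y) == n, length(classes) == n,
            train_fraction > 0, train_fraction <= 1)
  if (any(table(classes) < 3))
    stop("each class needs at least 3 members")
  idx_train <- with_seed(seed, {
    unlist(lapply(unique(classes), function(cl) {
      ids <- which(classes == cl)
      sample(ids, max(1, round(train_fraction * length(ids))))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- if (train_fraction == 1) idx_train else setdiff(seq_len(n), idx_train)
  w <- unname(weights_policy[classes])
  if (anyNA(w)) stop("weights_policy lacks an entry for some class")
  model <- fit_weighted_mlr(x[idx_train, , drop = FALSE], y[idx_train],
                            w[idx_train], weights_policy)
  pred_tr <- predict_pic50(model, x[idx_train, , drop = FALSE])
  pred_te <- predict_pic50(model, x[idx_test, , drop = FALSE])
  q2 <- loo_q2(x[idx_train, , drop = FALSE], y[idx_train], w[idx_train])$q2

  metrics <- function(obs, pred) {
    list(r2 = stats::cor(obs, pred)^2,
         r2_cod = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
         mae = mean(abs(obs - pred)), n = length(obs))
  }
  per_class <- function(idx, pred) {
    out <- lapply(unique(classes), function(cl) {
      sel <- classes[idx] == cl
      if (sum(sel) < 2) return(NULL)
      c(class = cl, metrics(y[idx][sel], pred[sel]))
    })
    out[!vapply(out, is.null, logical(1))]
  }
  structure(list(
    model = model,
    train = list(
      n = length(idx_train),
      r2 = wpearson2(y[idx_train], pred_tr, w[idx_train]),
      r2_cod = 1 - sum(w[idx_train] * (y[idx_train] - pred_tr)^2) /
        sum(w[idx_train] * (y[idx_train] - wmean(y[idx_train], w[idx_train]))^2),
      q2 = q2,
      mae = mean(abs(y[idx_train] - pred_tr)),
      by_class = per_class(idx_train, pred_tr)
    ),
    external = list(
      n = length(idx_test),
      r2 = stats::cor(y[idx_test], pred_te)^2,
      mae = mean(abs(y[idx_test] - pred_te)),
      by_class = per_class(idx_test, pred_te)
    ),
    split = list(train_fraction = train_fraction, seed = seed,
                 idx_train = idx_train)
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report: train n=%d R2=%.3f Q2=%.3f MAE=%.3f | external n=%d R2=%.3f MAE=%.3f>\n",
              x$train$n, x$train$r2, x$train$q2, x$train$mae,
              x$external$n, x$external$r2, x$external$mae))
  invisible(x)
}

#' Per-feature contribution decomposition of a prediction
#'
#' The product \eqn{c_i FP_i} is the independent contribution of feature i
#' to the predicted potency; contributions are grouped into hydrophobic
#' contact (FP9), hydrogen bonds (FP1-FP6) and heme interaction or
#' coordination (FP7, FP8).  The group totals plus the intercept reconcile
#' exactly with \code{\link{predict_pic50}}.
#'
#' @param model a \code{qsar_model}.
#' @param fp a fingerprint (named vector or one-row data.frame).
#' @param ligand_id optional identifier carried through.
#' @return list of class \code{contribution_profile} with
#'   \code{contributions} (named per-feature vector), \code{groups},
#'   \code{intercept}, \code{total}.
#' @export
contribution_profile <- function(model, fp, ligand_id = NA_character_) {
  x <- fp_matrix(fp, model$features)[1, ]
  contrib <- model$coefficients * x
  group_of <- c(FP1 = "hydrogen_bond", FP2 = "hydrogen_bond",
                FP3 = "hydrogen_bond", FP4 = "hydrogen_bond",
                FP5 = "hydrogen_bond", FP6 = "hydrogen_bond",
                FP7 = "heme", FP8 = "heme", FP9 = "hydrophobic")
  groups <- tapply(contrib, group_of[model$features], sum)
  total <- model$intercept + sum(contrib)
  structure(list(ligand_id = ligand_id, contributions = contrib,
                 groups = as.list(groups), intercept = model$intercept,
                 total = total),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat(sprintf("<contribution_profile %s: total %.3f (intercept %.3f)>\n",
              x$ligand_id, x$total, x$intercept))
  for (g in names(x$groups))
    cat(sprintf("  %-14s %8.3f\n", g, x$groups[[g]]))
  invisible(x)
}

# --- model persistence ------------------------------------------------------

#' Write / read a QSAR model as JSON
#' @param model a \code{qsar_model}.
#' @param path file path.
#' @export
write_qsar_model <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         weights_policy = as.list(model$weights_policy),
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  j <- jsonlite::fromJSON(path)
  qsar_model(features = j$features,
             coefficients = unlist(j$coefficients),
             intercept = j$intercept,
             weights_policy = unlist(j$weights_policy),
             provenance = j$provenance)
}
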