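#' Feature-name sets
#'
#' `pb_feature_names()` is the fixed 10-feature cross-information order used
#' by the propionate/butyrate network; `total_feature_names()` the five
#' total-route descriptors; `total_hier_feature_names()` the hierarchical
#' 7-feature order with the auxiliary P1/B1 concentrations appended.
#'
#' @return Character vector of feature names.
#' @export
pb_feature_names <- function() {
  c("B_I1", "B_I2", "B_V1", "B_V2", "B_A1", "B_A2",
    "C_I1", "C_I2", "C_V1", "C_A1")
}

#' @rdname pb_feature_names
#' @export
total_feature_names <- function() c("A_I1", "A_V1", "A_A1", "A_I2", "A_A2")

#' @rdname pb_feature_names
#' @export
total_hier_feature_names <- function() c(total_feature_names(), "P1", "B1")

.feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")))
  }
  as.matrix(data[, features, drop = FALSE])
}

# Targets are z-standardised (training statistics only) before optimisation so
# the Huber transition point and the Adam step size act on a unit scale across
# analytes; predictions are mapped back to mM. Constant targets keep sd 1.
.fit_target_scale <- function(y) {
  mu <- colMeans(y)
  sg <- apply(y, 2, stats::sd)
  sg[sg == 0] <- 1
  list(mu = mu, sd = sg)
}
.scale_targets <- function(ts, y) sweep(sweep(y, 2, ts$mu, "-"), 2, ts$sd, "/")
.unscale_targets <- function(ts, y) sweep(sweep(y, 2, ts$sd, "*"), 2, ts$mu, "+")

#' Train the two-output propionate/butyrate network
#'
#' One network predicting propionate and butyrate simultaneously from the
#' 10-feature cross-information vector. The min-max scaler is fitted on the
#' training rows only and embedded in the model, so prediction on new data
#' is leakage-free by construction.
#'
#' @param train data frame with the [pb_feature_names()] columns and the
#'   two target columns.
#' @param cfg an [mlp_config()]; defaults to the reduced profile (use
#'   [pb_mlp_config()] for the full published architecture).
#' @param targets names of the propionate and butyrate target columns, mM.
#' @param n_ensemble size of the initialisation committee: member networks
#'   are trained with seeds `cfg$seed, cfg$seed + 1, ...` and their
#'   predictions averaged. 1 reproduces a single network.
#' @return An object of class `pb_model`.
#' @export
train_pb_model <- function(train, cfg = reduced_mlp_config(),
                           targets = c("ref_prop", "ref_but"),
                           n_ensemble = 1L) {
  x <- .feature_matrix(train, pb_feature_names())
  y <- as.matrix(train[, targets, drop = FALSE])
  colnames(y) <- c("propionate", "butyrate")
  scaler <- fit_minmax(x)
  tscale <- .fit_target_scale(y)
  nets <- .train_committee(apply_minmax(scaler, x), .scale_targets(tscale, y),
                           cfg, n_ensemble)
  structure(list(nets = nets, scaler = scaler, tscale = tscale,
                 features = pb_feature_names(),
                 targets = targets), class = "pb_model")
}

.train_committee <- function(xs, ys, cfg, n_ensemble) {
  lapply(seq_len(n_ensemble), function(e) {
    cfg_e <- cfg
    cfg_e$seed <- cfg$seed + e - 1L
    net <- train_mlp(xs, ys, cfg_e)
    if (!all(is.finite(net$history))) stop("training diverged (non-finite loss)")
    net
  })
}

.predict_committee <- function(nets, xs) {
  Reduce(`+`, lapply(nets, predict, newdata = xs)) / length(nets)
}

#' @export
predict.pb_model <- function(object, newdata, ...) {
  x <- .feature_matrix(as.data.frame(newdata), object$features)
  .unscale_targets(object$tscale,
                   .predict_committee(object$nets, apply_minmax(object$scaler, x)))
}

#' Train the total-SCFA network
#'
#' Hierarchical by default: the propionate/butyrate model's predictions on
#' each training row are appended as auxiliary inputs P1/B1, raising the
#' input dimensionality from 5 to 7; the auxiliaries are scaled together
#' with the five descriptors by the total model's own scaler. With
#' `hierarchical = FALSE` a flat 5-feature model is fitted (the ablation
#' baseline).
#'
#' @param train data frame with the [total_feature_names()] columns, the
#'   `target` column, and (for the hierarchical design) the
#'   [pb_feature_names()] columns that `pb_model` consumes.
#' @param cfg an [mlp_config()]; use [total_mlp_config()] for the full
#'   published architecture.
#' @param pb_model a fitted [train_pb_model()] model (hierarchical only).
#' @param hierarchical logical.
#' @param target name of the total-SCFA target column, mM.
#' @param n_ensemble initialisation-committee size (see [train_pb_model()]).
#' @return An object of class `total_model`.
#' @export
train_total_model <- function(train, cfg = reduced_mlp_config(),
                              pb_model = NULL, hierarchical = TRUE,
                              target = "ref_total", n_ensemble = 1L) {
  x <- .feature_matrix(train, total_feature_names())
  if (hierarchical) {
    if (is.null(pb_model)) stop("hierarchical design requires a fitted pb_model")
    aux <- predict(pb_model, train)
    x <- cbind(x, P1 = aux[, "propionate"], B1 = aux[, "butyrate"])
  }
  y <- as.matrix(train[, target, drop = FALSE])
  colnames(y) <- "total"
  scaler <- fit_minmax(x)
  tscale <- .fit_target_scale(y)
  nets <- .train_committee(apply_minmax(scaler, x), .scale_targets(tscale, y),
                           cfg, n_ensemble)
  structure(list(nets = nets, scaler = scaler, tscale = tscale,
                 features = colnames(x), hierarchical = hierarchical,
                 pb_model = if (hierarchical) pb_model else NULL,
                 target = target), class = "total_model")
}

#' @export
predict.total_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  x <- .feature_matrix(newdata, total_feature_names())
  if (object$hierarchical) {
    aux <- predict(object$pb_model, newdata)
    x <- cbind(x, P1 = aux[, "propionate"], B1 = aux[, "butyrate"])
  }
  .unscale_targets(object$tscale,
                   .predict_committee(object$nets, apply_minmax(object$scaler, x)))[, 1]
}

#' Mass-balance acetate estimate
#'
#' Acetate as the residual total minus propionate minus butyrate. The
#' result may be negative (it is a reported residual, flagged downstream,
#' never clipped here).
#'
#' @param total,propionate,butyrate concentrations in mM (vectorised).
#' @return Acetate estimate in mM.
#' @export
acetate_mass_balance <- function(total, propionate, butyrate) {
  stopifnot(is.finite(total), is.finite(propionate), is.finite(butyrate))
  total - propionate - butyrate
}

#' Concentration set with exact mass-balance closure
#'
#' Holds the three predictions and the derived acetate estimate, which by
#' construction satisfies acetate = total - propionate - butyrate exactly.
#' Negative propionate/butyrate/total predictions are clipped to 0 and
#' flagged; a negative acetate residual is flagged but kept.
#'
#' @param propionate,butyrate,total predicted concentrations in mM.
#' @param clip logical; clip negative predictions (reporting convention).
#' @return An object of class `concentration_set`.
#' @export
concentration_set <- function(propionate, butyrate, total, clip = TRUE) {
  flags <- character(0)
  vals <- c(propionate = unname(propionate), butyrate = unname(butyrate),
            total = unname(total))
  if (clip && any(vals < 0)) {
    flags <- paste0(names(vals)[vals < 0], "_clipped")
    vals[vals < 0] <- 0
  }
  acetate <- acetate_mass_balance(vals[["total"]], vals[["propionate"]],
                                  vals[["butyrate"]])
  if (acetate < 0) flags <- c(flags, "negative_acetate_residual")
  structure(list(propionate = vals[["propionate"]],
                 butyrate = vals[["butyrate"]],
                 total = vals[["total"]],
                 acetate_est = acetate, flags = flags),
            class = "concentration_set")
}

#' @export
print.concentration_set <- function(x, ...) {
  cat(sprintf(
    "<concentration_set> propionate %.3f, butyrate %.3f, total %.3f, acetate_est %.3f mM%s\n",
    x$propionate, x$butyrate, x$total, x$acetate_est,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Hierarchical end-to-end prediction for one sample
#'
#' Predicts propionate and butyrate from the 10-feature cross-information
#' vector, feeds them as auxiliaries into the total-SCFA network, and
#' reports all three with the exact mass-balance acetate estimate.
#'
#' @param pb_model fitted [train_pb_model()] model.
#' @param total_model fitted hierarchical [train_total_model()] model.
#' @param p,b,t route feature objects from [extract_propionate_features()],
#'   [extract_butyrate_features()], [extract_total_features()].
#' @return A [concentration_set()].
#' @export
hierarchical_predict <- function(pb_model, total_model, p, b, t) {
  pb_vec <- assemble_pb_vector(p, b)
  row <- as.data.frame(as.list(c(pb_vec, unlist(unclass(t)))))
  pb_hat <- predict(pb_model, row)
  total_hat <- predict(total_model, row)
  concentration_set(pb_hat[1, "propionate"], pb_hat[1, "butyrate"], total_hat[1])
}

#' Multiple-linear-regression baseline
#'
#' Ordinary least squares on the same feature vectors, one response per
#' target column. Rank deficiency is reported as a warning with the
#' aliased coefficients set to zero at prediction.
#'
#' @param train data frame with feature and target columns.
#' @param features feature column names.
#' @param targets target column names.
#' @return An object of class `mlr_model` with the fitted [stats::lm()].
#' @export
train_mlr <- function(train, features, targets) {
  x <- .feature_matrix(train, features)
  if (nrow(x) < length(features) + 2L) stop("too few rows for MLR")
  y <- as.matrix(train[, targets, drop = FALSE])
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (anyNA(cf)) warning("rank-deficient design: aliased coefficients dropped")
  structure(list(fit = fit, features = features, targets = targets),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  x <- .feature_matrix(as.data.frame(newdata), object$features)
  cf <- stats::coef(object$fit)
  cf[is.na(cf)] <- 0
  cf <- as.matrix(cf)
  out <- cbind(1, x) %*% cf
  colnames(out) <- object$targets
  out
}

#' Random-forest baseline
#'
#' One seeded forest per target on the same feature vectors, with library
#' default hyperparameters.
#'
#' @param train data frame with feature and target columns.
#' @param features,targets column names.
#' @param seed integer seed.
#' @param ... passed to [randomForest::randomForest()].
#' @return An object of class `rf_model`.
#' @export
train_rf <- function(train, features, targets, seed = 1L, ...) {
  x <- .feature_matrix(train, features)
  forests <- lapply(targets, function(tg) {
    set.seed(seed)
    randomForest::randomForest(x, train[[tg]], ...)
  })
  names(forests) <- targets
  structure(list(forests = forests, features = features, targets = targets,
                 seed = seed), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  x <- .feature_matrix(as.data.frame(newdata), object$features)
  out <- vapply(object$forests, function(f) unname(predict(f, x)),
                numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(NULL, object$targets))
  out
}
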