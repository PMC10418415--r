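# Three-class (high / intermediate / low TdP risk) multinomial logistic
# model over the three CiPA-style predictors, ridge-penalized and fitted by
# a deterministic quasi-Newton optimizer (L-BFGS-B), mirroring the common
# scikit-learn recipe: full K-class softmax parameterization, penalty
# 1/(2C) * ||W||^2 on the weights only, iteration cap 1000.

#' Fit specification for the risk model
#'
#' @param penalty_strength_inverse Inverse ridge strength C (> 0); larger is
#'   weaker regularization. Default 1, the conventional default.
#' @param max_iterations Optimizer iteration cap (>= 1). Default 1000.
#' @param seed Integer seed recorded with the fit (the fit itself is
#'   deterministic).
#' @param feature_set Predictor columns used as the design matrix, in order.
#' @return Named list of class `fit_spec`.
#' @export
fit_spec <- function(penalty_strength_inverse = 1, max_iterations = 1000L,
                     seed = 0L,
                     feature_set = c("atype_score", "p80_at_cmax_norm",
                                     "p80_max_norm")) {
  stopifnot(penalty_strength_inverse > 0, max_iterations >= 1)
  structure(list(penalty_strength_inverse = penalty_strength_inverse,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), feature_set = feature_set),
            class = "fit_spec")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the multinomial TdP risk model
#'
#' Minimizes the multinomial negative log-likelihood plus
#' `1/(2C) * sum(W^2)` (intercepts unpenalized) over a full K-class softmax
#' parameterization, by L-BFGS-B with analytic gradients, starting from
#' zero. The fit is deterministic for fixed inputs and invariant to row
#' permutations.
#'
#' @param features Numeric matrix (n x p), rows = compounds.
#' @param labels Risk labels, coercible to a factor with levels
#'   `high`, `intermediate`, `low`; all three classes must be present.
#' @param spec A [fit_spec()].
#' @return Object of class `risk_model`: list with `weights` (K x p),
#'   `intercepts` (K), `classes`, `converged`, `iterations`, `spec`.
#' @export
fit_risk_model <- function(features, labels, spec = fit_spec()) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- factor(as.character(labels), levels = RISK_LEVELS)
  if (anyNA(y)) stop("labels must be high / intermediate / low")
  if (nlevels(droplevels(y)) < length(RISK_LEVELS)) {
    stop("all three risk classes must be present in the training labels")
  }
  n <- nrow(X); p <- ncol(X); K <- length(RISK_LEVELS)
  if (n < K) stop("need at least as many rows as classes")
  if (anyNA(X)) stop("features contain NA")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  C <- spec$penalty_strength_inverse
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(K * p)], K, p),
         b = theta[K * p + seq_len(K)])
  }
  obj <- function(theta) {
    par <- unpack(theta)
    Z <- X %*% t(par$W) + matrix(par$b, n, K, byrow = TRUE)
    P <- softmax_rows(Z)
    -sum(Y * log(pmax(P, 1e-300))) + sum(par$W^2) / (2 * C)
  }
  grad <- function(theta) {
    par <- unpack(theta)
    Z <- X %*% t(par$W) + matrix(par$b, n, K, byrow = TRUE)
    P <- softmax_rows(Z)
    R <- P - Y
    gW <- t(R) %*% X + par$W / C
    gb <- colSums(R)
    c(as.vector(gW), gb)
  }
  fit <- stats::optim(rep(0, K * p + K), fn = obj, gr = grad,
                      method = "L-BFGS-B",
                      control = list(maxit = spec$max_iterations,
                                     factr = 1e4))
  if (fit$convergence != 0) {
    warning("optimizer did not converge (code ", fit$convergence, ", ",
            fit$counts[1], " evaluations); returning current coefficients")
  }
  par <- unpack(fit$par)
  dimnames(par$W) <- list(RISK_LEVELS, colnames(X))
  names(par$b) <- RISK_LEVELS
  structure(list(weights = par$W, intercepts = par$b, classes = RISK_LEVELS,
                 converged = fit$convergence == 0,
                 iterations = unname(fit$counts[1]), spec = spec),
            class = "risk_model")
}

#' Predict per-compound TdP risk probabilities
#'
#' @param model A fitted `risk_model`.
#' @param features Numeric matrix (n x p) matching the fitted design width.
#' @param compounds Compound names, length n.
#' @param cell_line Cell-line tag carried into the output.
#' @param threshold Decision threshold on the combined (high +
#'   intermediate) probability; 0.8 per the CiPA convention.
#' @return Data frame of class `risk_prediction`: `compound`, `cell_line`,
#'   `prob_high`, `prob_intermediate`, `prob_low`, `combined_risk`
#'   (= prob_high + prob_intermediate) and `exceeds_threshold`
#'   (combined_risk > threshold).
#' @export
predict_risk <- function(model, features, compounds,
                         cell_line = NA_character_, threshold = 0.8) {
  X <- as.matrix(features)
  if (ncol(X) != ncol(model$weights)) {
    stop("feature width (", ncol(X), ") does not match the fitted model (",
         ncol(model$weights), ")")
  }
  Z <- X %*% t(model$weights) +
    matrix(model$intercepts, nrow(X), length(model$classes), byrow = TRUE)
  P <- softmax_rows(Z)
  out <- data.frame(compound = compounds, cell_line = cell_line,
                    prob_high = P[, "high"],
                    prob_intermediate = P[, "intermediate"],
                    prob_low = P[, "low"], stringsAsFactors = FALSE)
  out$combined_risk <- out$prob_high + out$prob_intermediate
  out$exceeds_threshold <- out$combined_risk > threshold
  class(out) <- c("risk_prediction", "data.frame")
  out
}

#' Stacked risk-probability bar chart
#'
#' One stacked bar per compound (high / intermediate / low in dark blue,
#' blue, light blue), with a dotted horizontal line at the decision
#' threshold. Deterministic for fixed input.
#'
#' @param predictions A `risk_prediction` data frame.
#' @param path Output `.svg` or `.pdf` path.
#' @param threshold Threshold line position (0.8 by default).
#' @return `path`, invisibly.
#' @export
plot_stacked_probabilities <- function(predictions, path, threshold = 0.8) {
  stopifnot(nrow(predictions) >= 1L)
  m <- t(as.matrix(predictions[, c("prob_high", "prob_intermediate",
                                   "prob_low")]))
  colnames(m) <- predictions$compound
  open_device(path, width = 8, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(8, 4, 3, 1))
  graphics::barplot(m, col = c("#08306b", "#2171b5", "#9ecae1"),
                    border = NA, las = 2, ylim = c(0, 1.05),
                    ylab = "TdP risk probability",
                    main = unique(predictions$cell_line)[1])
  graphics::abline(h = threshold, lty = 3, col = "red", lwd = 2)
  graphics::legend("topright", inset = c(0, -0.12), xpd = TRUE, bty = "n",
                   horiz = TRUE, fill = c("#08306b", "#2171b5", "#9ecae1"),
                   legend = c("high", "intermediate", "low"), cex = 0.8)
  invisible(path)
}

#' Run the full synthetic proarrhythmia pipeline
#'
#' Simulates a dosing plate for both cell lines, phenotypes every well,
#' builds and normalizes the predictor panels, fits one multinomial risk
#' model per cell line (in-sample prediction on the 11 training compounds,
#' faithful to the source analysis; `mode = "loo"` refits leaving each
#' compound out before predicting it, an extension that breaks the
#' circularity at the cost of very small training sets).
#'
#' @param registry A `cat_registry`.
#' @param seed Master seed for the plate simulation.
#' @param profiles,effects,replicates,duration,fs Passed to
#'   [simulate_plate()].
#' @param det_cfg,cls_cfg Detection and classification configurations.
#' @param spec A [fit_spec()].
#' @param mode `"insample"` (default) or `"loo"`.
#' @return List with `well_table`, `predictors` (named by line),
#'   `models` (named by line) and `predictions` (one data frame, both
#'   lines).
#' @export
run_risk_pipeline <- function(registry = load_registry(), seed = 1,
                              profiles = default_cell_profiles(),
                              effects = default_drug_effects(registry),
                              replicates = c(control = 6L, progeria = 4L),
                              duration = 30, fs = 50,
                              det_cfg = detection_config(),
                              cls_cfg = classifier_config(),
                              spec = fit_spec(),
                              mode = c("insample", "loo")) {
  mode <- match.arg(mode)
  plate <- simulate_plate(registry, profiles = profiles, effects = effects,
                          replicates = replicates, duration = duration,
                          fs = fs, seed = seed)
  wt <- phenotype_wells(plate$traces, det_cfg)
  predictors <- list(); models <- list(); preds <- list()
  for (line in names(profiles)) {
    ps <- build_predictor_set(wt, registry, line, cls_cfg)
    ps <- normalize_panel(ps)
    X <- as.matrix(ps[, spec$feature_set])
    rownames(X) <- ps$compound
    if (mode == "insample") {
      model <- fit_risk_model(X, ps$risk_label, spec)
      pr <- predict_risk(model, X, ps$compound, cell_line = line)
    } else {
      model <- fit_risk_model(X, ps$risk_label, spec)
      rows <- lapply(seq_len(nrow(X)), function(i) {
        m_i <- fit_risk_model(X[-i, , drop = FALSE], ps$risk_label[-i], spec)
        predict_risk(m_i, X[i, , drop = FALSE], ps$compound[i],
                     cell_line = line)
      })
      pr <- do.call(rbind, rows)
      class(pr) <- c("risk_prediction", "data.frame")
    }
    predictors[[line]] <- ps
    models[[line]] <- model
    preds[[line]] <- pr
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  class(predictions) <- c("risk_prediction", "data.frame")
  list(well_table = wt, predictors = predictors, models = models,
       predictions = predictions)
}
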