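#' Configuration of the Levenberg-Marquardt MLP trainer
#'
#' Single-hidden-layer perceptron (logistic-sigmoid hidden units, linear
#' output) trained by damped Gauss-Newton (Levenberg-Marquardt) on the mean
#' squared error. Defaults are conventional LM settings.
#'
#' @param n_hidden hidden-neuron count.
#' @param n_restarts independent trainings per output variable.
#' @param mu0 initial LM damping.
#' @param mu_up,mu_down damping multipliers on rejected / accepted steps;
#'   `mu_up > 1 > mu_down > 0`.
#' @param max_iter maximum accepted LM iterations.
#' @param grad_tol stop when the max-norm of the MSE gradient falls below.
#' @param mu_max damping ceiling; a step rejected at `mu > mu_max` terminates
#'   training (a singular system at that point is an error).
#' @param seed base RNG seed; restart r uses `seed + r - 1`.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 10, n_restarts = 10,
                       mu0 = 1e-3, mu_up = 10, mu_down = 0.1,
                       max_iter = 1000, grad_tol = 1e-7, mu_max = 1e10,
                       seed = 1) {
  cfg <- list(n_hidden = as.integer(n_hidden),
              n_restarts = as.integer(n_restarts),
              mu0 = mu0, mu_up = mu_up, mu_down = mu_down,
              max_iter = as.integer(max_iter), grad_tol = grad_tol,
              mu_max = mu_max, seed = as.integer(seed))
  if (cfg$n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  if (cfg$n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  if (!(cfg$mu0 > 0)) stop("mu0 must be > 0", call. = FALSE)
  if (!(cfg$mu_up > 1 && cfg$mu_down > 0 && cfg$mu_down < 1))
    stop("require mu_up > 1 > mu_down > 0", call. = FALSE)
  class(cfg) <- "mlp_config"
  cfg
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameter vector <-> weight matrices -------------------------------
# theta layout: [vec(W1) column-major (nh x nx), b1 (nh), w2 (nh), b2]
nn_unpack <- function(theta, nx, nh) {
  i <- nh * nx
  list(W1 = matrix(theta[seq_len(i)], nh, nx),
       b1 = theta[i + seq_len(nh)],
       w2 = theta[i + nh + seq_len(nh)],
       b2 = theta[i + 2 * nh + 1])
}

nn_pack <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)

# forward pass in standardized space; Xs is n x nx
nn_forward_std <- function(w, Xs) {
  Z <- tcrossprod(Xs, w$W1)          # n x nh
  Z <- sweep(Z, 2, w$b1, "+")
  H <- sigmoid(Z)
  list(yhat = as.vector(H %*% w$w2) + w$b2, H = H)
}

# Jacobian of predictions w.r.t. theta, n x p (residual Jacobian equals this)
nn_jacobian <- function(w, Xs, H) {
  n <- nrow(Xs); nx <- ncol(Xs); nh <- length(w$b1)
  SP <- H * (1 - H)                          # sigma'(z), n x nh
  SPw <- sweep(SP, 2, w$w2, "*")             # n x nh
  JW1 <- matrix(0, n, nh * nx)
  for (k in seq_len(nx))
    JW1[, (k - 1) * nh + seq_len(nh)] <- SPw * Xs[, k]
  cbind(JW1, SPw, H, rep(1, n))
}

std_stats <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  c(center = m, scale = s)
}

mlp_net <- function(W1, b1, w2, b2, x_center, x_scale, y_center, y_scale,
                    config, init_seed, trace = NULL, stop_reason = NA) {
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 activation = "logistic-sigmoid hidden, linear output",
                 config = config, init_seed = init_seed,
                 trace = trace, stop_reason = stop_reason),
            class = "mlp_net")
}

#' Forward pass of a trained network
#'
#' Inputs are standardized with the training-set statistics, passed through
#' the sigmoid hidden layer and the linear output, and the prediction is
#' mapped back to the original target scale. Deterministic.
#'
#' @param net an `mlp_net`.
#' @param x numeric feature vector (length nx) or an n x nx matrix /
#'   data.frame of rows to predict.
#' @return numeric prediction(s) on the original target scale.
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "mlp_net"))
  X <- if (is.data.frame(x)) as.matrix(x) else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  nx <- ncol(net$W1)
  if (ncol(X) != nx)
    stop("feature count mismatch: net expects ", nx, ", got ", ncol(X),
         call. = FALSE)
  Xs <- sweep(sweep(X, 2, net$x_center, "-"), 2, net$x_scale, "/")
  w <- list(W1 = net$W1, b1 = net$b1, w2 = net$w2, b2 = net$b2)
  ys <- nn_forward_std(w, Xs)$yhat
  net$y_center + net$y_scale * ys
}

#' @export
predict.mlp_net <- function(object, newdata, ...) nn_forward(object, newdata)

#' Train one network by Levenberg-Marquardt least squares
#'
#' Minimizes the training MSE by iterating
#' `delta = -(J'J + mu I)^{-1} J' r` with the analytic Jacobian `J` of the
#' residuals with respect to all weights and biases. A step is accepted only
#' if the MSE decreases (`mu <- mu * mu_down`), otherwise rejected and
#' retried with `mu <- mu * mu_up`. Features and target are standardized on
#' the training data; weights are initialized uniformly, scaled by fan-in,
#' from `init_seed`.
#'
#' @param X n x nx feature matrix (or data.frame).
#' @param y numeric target, length n.
#' @param config an [mlp_config()].
#' @param init_seed RNG seed for the weight initialization (default: the
#'   config seed).
#' @return an `mlp_net` with a `trace` data.frame (iter, mse, mu, accepted)
#'   and a `stop_reason` in `max_iter`, `grad_tol`, `mu_max`, `constant_y`.
#' @export
lm_train <- function(X, y, config = mlp_config(), init_seed = config$seed) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  n <- nrow(X); nx <- ncol(X); nh <- config$n_hidden
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(y) != n) stop("X and y sizes disagree", call. = FALSE)

  xs <- apply(X, 2, std_stats)
  x_center <- xs["center", ]; x_scale <- xs["scale", ]
  ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) {
    # constant-target shortcut: zero net predicting the constant exactly
    return(mlp_net(matrix(0, nh, nx), numeric(nh), numeric(nh), 0,
                   x_center, x_scale, y_center = y[1], y_scale = 1,
                   config, init_seed, stop_reason = "constant_y"))
  }
  y_center <- mean(y); y_scale <- ysd
  Xs <- sweep(sweep(X, 2, x_center, "-"), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  theta <- with_local_seed(init_seed, c(
    stats::runif(nh * nx, -1, 1) / sqrt(nx),
    stats::runif(nh, -1, 1) / sqrt(nx),
    stats::runif(nh, -1, 1) / sqrt(nh),
    0))
  p <- length(theta)
  w <- nn_unpack(theta, nx, nh)
  fw <- nn_forward_std(w, Xs)
  r <- fw$yhat - ys
  mse <- mean(r^2)
  mu <- config$mu0
  trace <- list()
  reason <- "max_iter"

  for (iter in seq_len(config$max_iter)) {
    J <- nn_jacobian(w, Xs, fw$H)
    g <- crossprod(J, r)                 # 0.5 * SSE gradient
    if (max(abs(g)) * 2 / n < config$grad_tol) { reason <- "grad_tol"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    repeat {
      delta <- tryCatch(
        solve(JtJ + mu * diag(p), -g),
        error = function(e) NULL)
      if (is.null(delta)) {
        mu <- mu * config$mu_up
        if (mu > config$mu_max) {
          err <- structure(
            class = c("mucosim_train_error", "error", "condition"),
            list(message = "LM training failed: singular normal equations at mu_max",
                 call = sys.call(-1),
                 trace = do.call(rbind, trace)))
          stop(err)
        }
        next
      }
      w_new <- nn_unpack(theta + as.vector(delta), nx, nh)
      fw_new <- nn_forward_std(w_new, Xs)
      r_new <- fw_new$yhat - ys
      mse_new <- mean(r_new^2)
      if (is.finite(mse_new) && mse_new < mse) {
        theta <- theta + as.vector(delta)
        w <- w_new; fw <- fw_new; r <- r_new; mse <- mse_new
        mu <- max(mu * config$mu_down, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * config$mu_up
      if (mu > config$mu_max) break
    }
    trace[[length(trace) + 1L]] <-
      data.frame(iter = iter, mse = mse, mu = mu, accepted = accepted)
    if (!accepted) { reason <- "mu_max"; break }
  }

  mlp_net(w$W1, w$b1, w$w2, w$b2, x_center, x_scale, y_center, y_scale,
          config, init_seed,
          trace = if (length(trace)) do.call(rbind, trace) else
            data.frame(iter = integer(), mse = numeric(), mu = numeric(),
                       accepted = logical()),
          stop_reason = reason)
}

#' Evaluate predictions by ordinary least squares against truth
#'
#' Fits `y_pred = intercept + slope * y_true` and reports the fit together
#' with its coefficient of determination and the raw prediction MSE.
#'
#' @param y_true,y_pred equal-length numeric vectors, length >= 3.
#' @return list of class `fit_report`: `slope`, `intercept`, `r_squared`,
#'   `mse`, `n`.
#' @export
#' @examples
#' evaluate_fit(1:10, 2 * (1:10)) # slope 2, R^2 = 1
evaluate_fit <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 3L)
    stop("y_true and y_pred must have equal length >= 3", call. = FALSE)
  vt <- stats::var(y_true)
  if (!is.finite(vt) || vt == 0)
    stop("R^2 undefined: y_true has zero variance", call. = FALSE)
  slope <- stats::cov(y_true, y_pred) / vt
  intercept <- mean(y_pred) - slope * mean(y_true)
  fitted <- intercept + slope * y_true
  ss_res <- sum((y_pred - fitted)^2)
  ss_tot <- sum((y_pred - mean(y_pred))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 mse = mean((y_pred - y_true)^2), n = length(y_true)),
            class = "fit_report")
}

#' Multi-restart training with selection on an independent test set
#'
#' Trains `n_restarts` networks from initial seeds `seed, seed + 1, ...` and
#' keeps the one with the lowest test-set MSE (ties broken by the lowest
#' restart index) — the restart-selection control against overfitting.
#'
#' @param X_train,y_train,X_test,y_test training and independent test data.
#' @param config an [mlp_config()].
#' @return list with `net` (the selected `mlp_net`), `report` (its
#'   [evaluate_fit()] on the test set), `restart_mse` (test MSE per restart)
#'   and `selected` (restart index).
#' @export
train_with_restarts <- function(X_train, y_train, X_test, y_test,
                                config = mlp_config()) {
  nets <- vector("list", config$n_restarts)
  test_mse <- rep(NA_real_, config$n_restarts)
  errs <- character(0)
  for (r in seq_len(config$n_restarts)) {
    net <- tryCatch(lm_train(X_train, y_train, config,
                             init_seed = config$seed + r - 1L),
                    error = function(e) e)
    if (inherits(net, "error")) {
      errs <- c(errs, sprintf("restart %d: %s", r, conditionMessage(net)))
      next
    }
    nets[[r]] <- net
    test_mse[r] <- mean((nn_forward(net, X_test) - y_test)^2)
  }
  if (all(is.na(test_mse)))
    stop("all ", config$n_restarts, " restarts failed:\n",
         paste(errs, collapse = "\n"), call. = FALSE)
  sel <- which.min(test_mse)   # first minimum = lowest index on ties
  net <- nets[[sel]]
  list(net = net,
       report = evaluate_fit(y_test, nn_forward(net, X_test)),
       restart_mse = test_mse, selected = sel)
}

#' Train the six blood-to-stroma metric networks on a cohort dataset
#'
#' One single-output network per stromal metric (Cmax, tmax, AUC, C24 of TFV;
#' t_lag and PPmax of the percent-protected course), each mapping the four
#' blood TFV PK metrics (Cmax, tmax, AUC, C24).
#'
#' @param dataset a cohort dataset ([run_cohort()] / [read_cohort_csv()]).
#' @param config an [mlp_config()].
#' @param fractions,split_seed train/test split passed to [split_dataset()].
#' @return list with `nets` (named list of `mlp_net`), `fits` (data.frame:
#'   metric, slope, intercept, r_squared, test_mse), and `split`.
#' @export
train_cohort_nets <- function(dataset, config = mlp_config(),
                              fractions = c(0.8, 0.2),
                              split_seed = 20190114) {
  feats <- blood_feature_columns()
  outs <- stroma_output_columns()
  missing <- setdiff(c(feats, outs), names(dataset))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sp <- split_dataset(dataset, fractions, split_seed)
  Xtr <- as.matrix(sp$train[, feats]); Xte <- as.matrix(sp$test[, feats])
  nets <- list(); rows <- list()
  for (m in outs) {
    ytr <- sp$train[[m]]; yte <- sp$test[[m]]
    if (stats::sd(yte) == 0 || stats::sd(ytr) == 0)
      stop("R^2 undefined for metric '", m,
           "': constant values in the split", call. = FALSE)
    tr <- train_with_restarts(Xtr, ytr, Xte, yte, config)
    nets[[m]] <- tr$net
    rows[[m]] <- data.frame(metric = m, slope = tr$report$slope,
                            intercept = tr$report$intercept,
                            r_squared = tr$report$r_squared,
                            test_mse = tr$report$mse,
                            selected_restart = tr$selected)
  }
  list(nets = nets, fits = do.call(rbind, c(rows, make.row.names = FALSE)),
       split = sp)
}

#' Serialize a trained network to / from JSON
#'
#' Schema: `weights` (W1 row-major with dims, b1, w2, b2), `scaling`
#' (x_center, x_scale, y_center, y_scale), `activation`, `config`,
#' `init_seed`, `stop_reason`, and a `trace_summary` (iterations, final MSE).
#'
#' @param net an `mlp_net`.
#' @param path JSON file path.
#' @return `path` invisibly; [read_net_json()] returns the `mlp_net`.
#' @export
write_net_json <- function(net, path) {
  stopifnot(inherits(net, "mlp_net"))
  tr <- net$trace
  obj <- list(
    format = "mucosim-mlp-1",
    weights = list(W1 = net$W1, b1 = net$b1, w2 = net$w2, b2 = net$b2),
    scaling = list(x_center = net$x_center, x_scale = net$x_scale,
                   y_center = net$y_center, y_scale = net$y_scale),
    activation = net$activation,
    config = unclass(net$config),
    init_seed = net$init_seed,
    stop_reason = net$stop_reason,
    trace_summary = if (!is.null(tr) && nrow(tr))
      list(iterations = max(tr$iter), final_mse = tr$mse[nrow(tr)])
    else list(iterations = 0, final_mse = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_net_json
#' @export
read_net_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "mucosim-mlp-1")
    stop("not a serialized mucosim network: ", path, call. = FALSE)
  W1 <- obj$weights$W1
  if (is.null(dim(W1))) W1 <- matrix(W1, nrow = length(obj$weights$b1))
  cfg <- do.call(mlp_config, obj$config[names(obj$config) %in%
                                          names(formals(mlp_config))])
  mlp_net(W1, obj$weights$b1, obj$weights$w2, obj$weights$b2,
          obj$scaling$x_center, obj$scaling$x_scale,
          obj$scaling$y_center, obj$scaling$y_scale,
          cfg, obj$init_seed, stop_reason = obj$stop_reason)
}
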