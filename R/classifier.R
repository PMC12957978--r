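#' Default classifier feature set
#'
#' The six AUC network properties used as classifier inputs: modularity,
#' local and rich-club connection strengths, global and local efficiency
#' and characteristic path length. `all_features()` additionally includes
#' the clustering coefficient and feeder connection strength.
#'
#' @return Character vector of feature names.
#' @export
classifier_features <- function() {
  c("aQ", "Local_s", "Rich_s", "aEg", "aEloc", "aLp")
}

#' @rdname classifier_features
#' @export
all_features <- function() {
  c("aCp", "aEg", "aEloc", "aLp", "aQ", "Rich_s", "Local_s", "Feeder_s")
}

#' Class-stratified train / test / validation split
#'
#' Splits records into disjoint sets with class-wise proportions matching
#' `ratios` (largest-remainder apportionment per class), so the class
#' ratio of every set is within one record of the global ratio.
#'
#' @param records Data frame with a `label` column.
#' @param ratios Numeric vector of set proportions summing to 1
#'   (default 0.8 / 0.1 / 0.1 for train / test / validation).
#' @param seed Integer seed.
#' @return List of data frames `train`, `test`, `validation`.
#' @export
stratified_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  n_sets <- length(ratios)
  labs <- as.character(records$label)
  assign_set <- integer(nrow(records))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    if (length(idx) < n_sets) {
      stop("class '", cl, "' has fewer records (", length(idx),
           ") than sets (", n_sets, ")")
    }
    idx <- .with_seed(.derive_seed(seed, match(cl, unique(labs))), sample(idx))
    quota <- floor(length(idx) * ratios)
    rem <- length(idx) - sum(quota)
    if (rem > 0) {
      frac <- length(idx) * ratios - quota
      extra <- order(-frac, seq_along(ratios))[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    bounds <- cumsum(c(0L, quota))
    for (s in seq_len(n_sets)) {
      if (quota[s] > 0) {
        assign_set[idx[(bounds[s] + 1L):bounds[s + 1L]]] <- s
      }
    }
  }
  out <- lapply(seq_len(n_sets), function(s) records[assign_set == s, , drop = FALSE])
  names(out) <- c("train", "test", "validation")[seq_len(n_sets)]
  out
}

# ---- MLP internals -------------------------------------------------------

.mlp_init <- function(layer_sizes, seed) {
  .with_seed(seed, {
    lapply(seq_len(length(layer_sizes) - 1L), function(l) {
      fan_in <- layer_sizes[l]
      list(W = matrix(stats::rnorm(fan_in * layer_sizes[l + 1L],
                                   sd = 1 / sqrt(fan_in)),
                      fan_in, layer_sizes[l + 1L]),
           b = rep(0, layer_sizes[l + 1L]))
    })
  })
}

.mlp_flatten <- function(params) {
  unlist(lapply(params, function(p) c(as.numeric(p$W), p$b)))
}

.mlp_unflatten <- function(theta, layer_sizes) {
  params <- vector("list", length(layer_sizes) - 1L)
  pos <- 0L
  for (l in seq_along(params)) {
    nin <- layer_sizes[l]
    nout <- layer_sizes[l + 1L]
    params[[l]] <- list(
      W = matrix(theta[pos + seq_len(nin * nout)], nin, nout),
      b = theta[pos + nin * nout + seq_len(nout)]
    )
    pos <- pos + nin * nout + nout
  }
  params
}

# forward pass; returns softmax probabilities and hidden activations
.mlp_forward <- function(params, x) {
  a <- x
  acts <- list(a)
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- a %*% params[[l]]$W + matrix(params[[l]]$b, nrow(a),
                                      length(params[[l]]$b), byrow = TRUE)
    a <- if (l < n_layers) tanh(z) else z
    acts[[l + 1L]] <- a
  }
  z <- acts[[n_layers + 1L]]
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, acts = acts)
}

# mean softmax cross-entropy
.mlp_loss <- function(params, x, y_onehot) {
  p <- .mlp_forward(params, x)$probs
  -mean(rowSums(y_onehot * log(pmax(p, 1e-300))))
}

# gradient of the mean cross-entropy, flattened
.mlp_grad <- function(params, x, y_onehot) {
  fw <- .mlp_forward(params, x)
  n <- nrow(x)
  n_layers <- length(params)
  delta <- (fw$probs - y_onehot) / n
  grads <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = t(a_prev) %*% delta, b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (1 - fw$acts[[l]]^2)
    }
  }
  .mlp_flatten(grads)
}

# Scaled conjugate gradient minimisation (Moller 1993), full batch.
# fn/gr take the flat parameter vector. Returns the iterate history needed
# for early stopping via the callback, which is invoked after every
# accepted step with (theta, loss) and may return TRUE to stop.
.scg_optimise <- function(theta, fn, gr, max_epochs = 1000, sigma = 1e-4,
                          lambda = 1e-6, callback = NULL) {
  n_par <- length(theta)
  lambda_bar <- 0
  r <- -gr(theta)
  p <- r
  success <- TRUE
  f_cur <- fn(theta)
  log_epochs <- integer(0)
  log_loss <- numeric(0)
  delta <- 0
  s <- numeric(n_par)
  for (k in seq_len(max_epochs)) {
    p2 <- sum(p * p)
    if (p2 < 1e-300 || sum(r * r) < 1e-20) break
    if (success) {
      sigma_k <- sigma / sqrt(p2)
      s <- (gr(theta + sigma_k * p) - gr(theta)) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(theta + alpha * p)
    Delta <- 2 * delta * (f_cur - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- theta + alpha * p
      f_cur <- f_new
      r_new <- -gr(theta)
      lambda_bar <- 0
      success <- TRUE
      if (k %% n_par == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      log_epochs <- c(log_epochs, k)
      log_loss <- c(log_loss, f_cur)
      if (!is.null(callback) && isTRUE(callback(theta, f_cur))) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) {
      lambda <- lambda + delta * (1 - Delta) / p2
    }
    if (lambda > 1e100) break
  }
  list(theta = theta, loss = f_cur,
       log = data.frame(epoch = log_epochs, train_ce = log_loss))
}

#' Train the MLP cognitive-status classifier with scaled conjugate gradient
#'
#' A feed-forward network with three hidden layers of six tanh units and a
#' two-unit softmax output, trained full-batch by scaled conjugate
#' gradients on the softmax cross-entropy, with no regularisation.
#' Features are standardised with the training-set mean and SD only (the
#' parameters are stored in the model and applied at prediction time).
#' Training stops at `max_epochs` or after `max_fail` consecutive
#' increases of the validation cross-entropy, returning the weights with
#' the best validation loss. Seeded weight initialisation makes training
#' deterministic.
#'
#' @param train Data frame of training records (feature columns + `label`).
#' @param validation Optional validation data frame for early stopping.
#' @param feature_names Feature columns to use
#'   (default [classifier_features()]).
#' @param hidden Hidden layer sizes (default `c(6, 6, 6)`).
#' @param max_epochs Maximum SCG iterations (default 1000).
#' @param max_fail Consecutive validation failures before stopping
#'   (default 6).
#' @param sigma,lambda0 SCG constants (second-order step size 1e-4 and
#'   initial scale parameter 1e-6).
#' @param seed Integer seed.
#' @return An `mlp_model`: list with `params`, `layer_sizes`, `classes`,
#'   `feature_names`, `center`/`scale` standardisation vectors and a
#'   `training_log` (accepted-step epochs, training and validation
#'   cross-entropy).
#' @export
train_scg_mlp <- function(train, validation = NULL,
                          feature_names = classifier_features(),
                          hidden = c(6, 6, 6), max_epochs = 1000L,
                          max_fail = 6L, sigma = 1e-4, lambda0 = 1e-6,
                          seed = 1L) {
  miss <- setdiff(feature_names, names(train))
  if (length(miss) > 0) stop("missing feature columns: ", paste(miss, collapse = ", "))
  x <- as.matrix(train[feature_names])
  if (any(!is.finite(x))) stop("non-finite training features")
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  zero_var <- feature_names[scale_ == 0 | !is.finite(scale_)]
  if (length(zero_var) > 0) {
    stop("zero-variance feature(s) on the training set: ",
         paste(zero_var, collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  classes <- sort(unique(as.character(train$label)))
  if (length(classes) < 2) stop("training set must contain both classes")
  y <- match(as.character(train$label), classes)
  y_onehot <- diag(length(classes))[y, , drop = FALSE]
  layer_sizes <- c(length(feature_names), hidden, length(classes))
  params0 <- .mlp_init(layer_sizes, seed)
  theta0 <- .mlp_flatten(params0)
  fn <- function(th) .mlp_loss(.mlp_unflatten(th, layer_sizes), xs, y_onehot)
  gr <- function(th) .mlp_grad(.mlp_unflatten(th, layer_sizes), xs, y_onehot)

  val_env <- NULL
  callback <- NULL
  if (!is.null(validation) && nrow(validation) > 0) {
    xv <- as.matrix(validation[feature_names])
    xvs <- sweep(sweep(xv, 2, center), 2, scale_, "/")
    yv <- match(as.character(validation$label), classes)
    yv_onehot <- diag(length(classes))[yv, , drop = FALSE]
    val_env <- new.env()
    val_env$best <- Inf
    val_env$best_theta <- theta0
    val_env$fails <- 0L
    val_env$val_ce <- numeric(0)
    callback <- function(theta, loss) {
      vce <- .mlp_loss(.mlp_unflatten(theta, layer_sizes), xvs, yv_onehot)
      val_env$val_ce <- c(val_env$val_ce, vce)
      if (vce < val_env$best) {
        val_env$best <- vce
        val_env$best_theta <- theta
        val_env$fails <- 0L
      } else {
        val_env$fails <- val_env$fails + 1L
      }
      val_env$fails >= max_fail
    }
  }
  opt <- .scg_optimise(theta0, fn, gr, max_epochs = max_epochs,
                       sigma = sigma, lambda = lambda0, callback = callback)
  theta_final <- if (!is.null(val_env)) val_env$best_theta else opt$theta
  log <- opt$log
  if (!is.null(val_env)) log$val_ce <- val_env$val_ce
  structure(list(
    params = .mlp_unflatten(theta_final, layer_sizes),
    layer_sizes = layer_sizes,
    classes = classes,
    feature_names = feature_names,
    center = center,
    scale = scale_,
    training_log = log,
    final_train_ce = opt$loss
  ), class = "mlp_model")
}

#' Classify a feature vector with a trained MLP
#'
#' Standardises the features with the stored training-set parameters,
#' runs the forward pass and returns the argmax label with its softmax
#' probability. Deterministic.
#'
#' @param model An `mlp_model` from [train_scg_mlp()].
#' @param features Named numeric vector (or single-row data frame / matrix
#'   of the model's feature columns).
#' @return List with `label`, `probability` (of the predicted label) and
#'   `probs` (named probability vector over both classes).
#' @export
predict_mlp <- function(model, features) {
  if (is.data.frame(features)) {
    x <- as.matrix(features[model$feature_names])
  } else if (is.matrix(features)) {
    x <- features[, model$feature_names, drop = FALSE]
  } else {
    if (!is.null(names(features))) features <- features[model$feature_names]
    x <- matrix(as.numeric(features), nrow = 1)
  }
  if (any(!is.finite(x))) stop("non-finite features")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  probs <- .mlp_forward(model$params, xs)$probs
  if (nrow(probs) == 1) {
    p <- as.numeric(probs)
    names(p) <- model$classes
    k <- which.max(p)
    list(label = model$classes[k], probability = p[[k]], probs = p)
  } else {
    colnames(probs) <- model$classes
    k <- max.col(probs, ties.method = "first")
    list(label = model$classes[k], probability = probs[cbind(seq_len(nrow(probs)), k)],
         probs = probs)
  }
}

#' ROC curve and area for a trained classifier
#'
#' Sweeps a threshold over the predicted probability of the positive
#' class and reports the (FPR, TPR) operating points and the trapezoidal
#' area. With tied scores the curve has diagonal segments, so the area
#' equals the Mann-Whitney pairwise-concordance probability.
#'
#' @param model An `mlp_model`.
#' @param records Data frame with the model's feature columns and `label`;
#'   both classes must be present.
#' @param positive Which class counts as positive (default: the second of
#'   the model's sorted classes).
#' @return List with `points` (data frame of FPR, TPR ordered along the
#'   sweep) and `area`.
#' @export
roc_curve <- function(model, records, positive = NULL) {
  if (is.null(positive)) positive <- model$classes[2]
  labs <- as.character(records$label)
  if (length(unique(labs)) < 2) stop("ROC requires records from both classes")
  pred <- predict_mlp(model, records)
  scores <- if (is.matrix(pred$probs)) pred$probs[, positive] else pred$probs[positive]
  .roc_from_scores(scores, labs == positive)
}

# threshold sweep shared by roc_curve and tests on raw scores
.roc_from_scores <- function(scores, is_pos) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_pos) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_pos) / nn, numeric(1))
  fpr <- c(0, fpr)
  tpr <- c(0, tpr)
  if (utils::tail(fpr, 1) < 1 || utils::tail(tpr, 1) < 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(FPR = fpr, TPR = tpr), area = area)
}

#' Serialise / restore an MLP model as JSON
#'
#' @param model An `mlp_model`.
#' @param path File path.
#' @return `path` invisibly for write; an `mlp_model` for read.
#' @export
write_mlp_model <- function(model, path) {
  obj <- list(
    layer_sizes = model$layer_sizes,
    classes = model$classes,
    feature_names = model$feature_names,
    center = as.numeric(model$center),
    scale = as.numeric(model$scale),
    params = lapply(model$params, function(p) {
      list(W = as.numeric(p$W), dim = dim(p$W), b = p$b)
    }),
    training_log = model$training_log,
    final_train_ce = model$final_train_ce
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(seq_len(length(obj$layer_sizes) - 1L), function(l) {
    p <- if (is.data.frame(obj$params)) obj$params[l, ] else obj$params[[l]]
    W <- matrix(unlist(p$W), unlist(p$dim)[1], unlist(p$dim)[2])
    list(W = W, b = unlist(p$b))
  })
  structure(list(
    params = params,
    layer_sizes = as.integer(obj$layer_sizes),
    classes = obj$classes,
    feature_names = obj$feature_names,
    center = stats::setNames(obj$center, obj$feature_names),
    scale = stats::setNames(obj$scale, obj$feature_names),
    training_log = as.data.frame(obj$training_log),
    final_train_ce = obj$final_train_ce
  ), class = "mlp_model")
}
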