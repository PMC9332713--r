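# Per-subject verification networks: one hidden tanh layer, two linear
# outputs (genuine score, impostor score), trained to +/-1 target codes
# under mean squared error with Levenberg-Marquardt damping.

# Pack/unpack parameters: [vec(W1) h x d, b1 h, vec(W2) 2 x h, b2 2].
unpack_params <- function(theta, d, h) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(h * d)], h, d); i <- i + h * d
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(2 * h)], 2, h); i <- i + 2 * h
  b2 <- theta[i + seq_len(2)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# Forward pass. X: n x d (already standardized). Returns Y (n x 2) and
# the hidden activations Z (n x h).
nn_forward <- function(par, X) {
  A <- X %*% t(par$W1)
  A <- sweep(A, 2, par$b1, "+")
  Z <- tanh(A)
  Y <- Z %*% t(par$W2)
  Y <- sweep(Y, 2, par$b2, "+")
  list(Y = Y, Z = Z)
}

# Jacobian of the stacked residual vector r = vec(Y - T) (rows: n
# samples for output 1, then n samples for output 2) with respect to
# the packed parameters. n x d inputs, h hidden units -> (2n) x p.
nn_jacobian <- function(par, X, Z) {
  n <- nrow(X); d <- ncol(X); h <- ncol(Z)
  D <- 1 - Z^2 # tanh'
  p <- h * d + h + 2 * h + 2
  J <- matrix(0, 2 * n, p)
  for (j in seq_len(h)) {
    cols <- ((j - 1) * d + 1):(j * d)
    # dY_k/dW1[j,] = W2[k,j] * D[,j] * X
    J[seq_len(n), cols] <- (par$W2[1, j] * D[, j]) * X
    J[n + seq_len(n), cols] <- (par$W2[2, j] * D[, j]) * X
    # biases b1
    J[seq_len(n), h * d + j] <- par$W2[1, j] * D[, j]
    J[n + seq_len(n), h * d + j] <- par$W2[2, j] * D[, j]
  }
  # W2 (2 x h), column-major: (k, j) at h*d + h + (j-1)*2 + k
  for (j in seq_len(h)) {
    J[seq_len(n), h * d + h + (j - 1) * 2 + 1] <- Z[, j]
    J[n + seq_len(n), h * d + h + (j - 1) * 2 + 2] <- Z[, j]
  }
  J[seq_len(n), h * d + h + 2 * h + 1] <- 1
  J[n + seq_len(n), h * d + h + 2 * h + 2] <- 1
  J
}

nn_init <- function(d, h, seed) {
  with_seed(seed, {
    c(stats::runif(h * d, -0.5, 0.5) / sqrt(d),
      stats::runif(h, -0.5, 0.5),
      stats::runif(2 * h, -0.5, 0.5) / sqrt(h),
      stats::runif(2, -0.5, 0.5))
  })
}

#' Train one verification network with Levenberg-Marquardt
#'
#' Fits a feedforward network with one hidden tanh layer and two linear
#' output neurons to +/-1 target codes (genuine = (+1, -1), impostor =
#' (-1, +1)) by minimizing mean squared error with Levenberg-Marquardt
#' damping: each iteration solves `(J'J + mu I) delta = J' r`, with `mu`
#' multiplied by 0.1 after an accepted step and by 10 after a rejected
#' one. Accepted-step MSE is therefore non-increasing. Training inputs
#' are standardized (per-feature center and scale estimated from the
#' training data only) and the standardization is stored in the model,
#' so prediction is self-contained and never touches test statistics.
#'
#' @param X numeric matrix n x d of training feature vectors (raw,
#'   unstandardized).
#' @param labels character or logical vector: `"genuine"`/`TRUE` vs
#'   `"impostor"`/`FALSE`, one per row of `X`.
#' @param n_hidden number of hidden neurons (1--10 in the study grid).
#' @param seed integer seed for the weight initialization.
#' @param max_iter maximum LM iterations.
#' @param tol gradient infinity-norm stopping tolerance.
#' @param mu0,mu_max initial and maximal damping.
#' @return Object of class `verifier_model`: weights, standardization
#'   parameters (`center`, `scale`), `n_hidden`, `final_mse`,
#'   `train_accuracy`, `converged` flag, `iterations`, `seed`.
#' @export
train_lm <- function(X, labels, n_hidden = 1, seed = 1,
                     max_iter = 100, tol = 1e-7,
                     mu0 = 1e-3, mu_max = 1e10) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("training inputs must be finite")
  lab <- normalize_labels(labels)
  if (length(lab) != nrow(X)) stop("one label per training row required")
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  Tm <- cbind(ifelse(lab, 1, -1), ifelse(lab, -1, 1))

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")

  d <- ncol(Xs); h <- as.integer(n_hidden); n <- nrow(Xs)
  theta <- nn_init(d, h, seed)
  par <- unpack_params(theta, d, h)
  fwd <- nn_forward(par, Xs)
  r <- as.vector(fwd$Y - Tm) # column-major: output 1 rows then output 2
  mse <- mean(r^2)

  mu <- mu0
  converged <- FALSE
  stalled <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- nn_jacobian(par, Xs, fwd$Z)
    g <- crossprod(J, r)
    if (max(abs(g)) / length(r) < tol) { converged <- TRUE; break }
    H <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= mu_max) {
      delta <- tryCatch(
        solve(H + diag(mu, nrow(H)), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        theta_try <- theta - as.vector(delta)
        par_try <- unpack_params(theta_try, d, h)
        fwd_try <- nn_forward(par_try, Xs)
        r_try <- as.vector(fwd_try$Y - Tm)
        mse_try <- mean(r_try^2)
        if (is.finite(mse_try) && mse_try < mse) {
          theta <- theta_try; par <- par_try; fwd <- fwd_try
          r <- r_try; mse <- mse_try
          mu <- mu * 0.1
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * 10
    }
    if (!accepted) { stalled <- TRUE; break } # mu overflow: no improving step
  }

  model <- structure(list(
    W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
    center = center, scale = scale,
    n_hidden = h, input_dim = d,
    final_mse = mse, iterations = iter,
    converged = converged, stalled = stalled, seed = seed
  ), class = "verifier_model")
  model$train_accuracy <-
    mean(predict(model, X)$label == ifelse(lab, "genuine", "impostor"))
  model
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("genuine", "impostor"))) {
      stop("labels must be 'genuine' or 'impostor'")
    }
    return(labels == "genuine")
  }
  stop("labels must be logical or 'genuine'/'impostor'")
}

#' Best-of-n restart training
#'
#' Runs `n_restarts` independent Levenberg-Marquardt fits from different
#' seeded initializations and keeps the network with the highest
#' training accuracy; ties are broken by lower final MSE. Restart seeds
#' are derived deterministically from `seed`.
#'
#' @inheritParams train_lm
#' @param n_restarts number of restarts (study default 10).
#' @param ... passed to [train_lm()].
#' @return The selected `verifier_model`, with `restart_accuracies`
#'   recording every restart's training accuracy.
#' @export
train_best_of <- function(X, labels, n_hidden = 1, n_restarts = 10,
                          seed = 1, ...) {
  fits <- lapply(seq_len(n_restarts), function(r) {
    train_lm(X, labels, n_hidden = n_hidden,
             seed = derive_seed(seed, "restart", r), ...)
  })
  acc <- vapply(fits, `[[`, numeric(1), "train_accuracy")
  mse <- vapply(fits, `[[`, numeric(1), "final_mse")
  best <- order(-acc, mse)[1]
  out <- fits[[best]]
  out$restart_accuracies <- acc
  out
}

#' Predict genuine/impostor labels
#'
#' Standardizes inputs with the model's stored training statistics and
#' labels a vector genuine iff its genuine output score strictly exceeds
#' its impostor score; exact ties go to impostor (the conservative
#' choice for a verification system).
#'
#' @param object a `verifier_model`.
#' @param newdata numeric matrix (or single vector) of raw feature
#'   vectors with `input_dim` columns.
#' @param ... unused.
#' @return List with `label` (character vector) and `scores` (n x 2
#'   matrix: genuine score, impostor score).
#' @export
predict.verifier_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    stop(sprintf("input has %d features, model expects %d", ncol(X),
                 object$input_dim))
  }
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  Y <- nn_forward(object, Xs)$Y
  colnames(Y) <- c("genuine", "impostor")
  list(label = ifelse(Y[, 1] > Y[, 2], "genuine", "impostor"),
       scores = Y)
}

#' @export
print.verifier_model <- function(x, ...) {
  cat(sprintf(
    "<verifier_model> %d inputs -> %d tanh hidden -> 2 linear outputs; train acc %.3f, MSE %.4g (%d LM iterations%s)\n",
    x$input_dim, x$n_hidden, x$train_accuracy, x$final_mse, x$iterations,
    if (isTRUE(x$converged)) "" else ", not converged"))
  invisible(x)
}

#' Save / load a verifier model as JSON
#'
#' Single-file plain-text serialization of the weights, standardization
#' parameters and training metadata.
#'
#' @param model a `verifier_model`.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_verifier_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_verifier_json
#' @export
read_verifier_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), nr, nc, byrow = TRUE)
  }
  m$W1 <- as_mat(m$W1, m$n_hidden, m$input_dim)
  m$W2 <- as_mat(m$W2, 2, m$n_hidden)
  structure(m, class = "verifier_model")
}
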