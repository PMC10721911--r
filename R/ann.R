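# Fully-connected feed-forward network with logistic activations throughout
# and a logistic output unit, trained by BFGS on the penalized binomial
# cross-entropy with analytic backpropagated gradients. Small nets on small
# tabular data; no stochastic minibatching needed.

#' Specify a propensity network architecture
#'
#' @param hidden integer vector of hidden-layer sizes (1 to 3 layers, every
#'   layer >= 1 node).
#' @param max_iterations BFGS iteration cap per restart.
#' @param tol relative convergence tolerance on the penalized loss.
#' @param seed seed for weight initialization.
#' @param input_scaling `"minmax"` (per-item to \[0,1\], the default — keeps
#'   the sigmoids in their responsive range) or `"zscore"`.
#' @param decay L2 weight-decay coefficient; a small ridge penalty keeps the
#'   tiny-sample fits from saturating.
#' @param restarts further random initializations tried on non-convergence.
#' @return an object of class `ann_spec`.
#' @export
ann_spec <- function(hidden = 3, max_iterations = 500, tol = 1e-8, seed = 1,
                     input_scaling = c("minmax", "zscore"), decay = 1e-3,
                     restarts = 5) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden < 1)) {
    stop("hidden must give 1-3 layers with >= 1 node each")
  }
  structure(
    list(
      hidden = hidden, max_iterations = as.integer(max_iterations),
      tol = tol, seed = as.integer(seed),
      input_scaling = match.arg(input_scaling), decay = decay,
      restarts = as.integer(restarts)
    ),
    class = "ann_spec"
  )
}

#' @export
print.ann_spec <- function(x, ...) {
  cat(sprintf(
    "<ann_spec> hidden %s, %s scaling, decay %g, seed %d\n",
    paste(x$hidden, collapse = "-"), x$input_scaling, x$decay, x$seed
  ))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# flatten / unflatten parameters -----------------------------------------

ann_layer_sizes <- function(n_in, hidden) c(n_in, hidden, 1L)

ann_unflatten <- function(par, sizes) {
  W <- list()
  b <- list()
  pos <- 0L
  for (l in seq_len(length(sizes) - 1)) {
    nw <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(par[pos + seq_len(nw)], sizes[l], sizes[l + 1])
    pos <- pos + nw
    b[[l]] <- par[pos + seq_len(sizes[l + 1])]
    pos <- pos + sizes[l + 1]
  }
  list(W = W, b = b)
}

ann_forward <- function(x, W, b) {
  a <- list(x)
  L <- length(W)
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
    a[[l + 1]] <- sigmoid(z)
  }
  a
}

# penalized cross-entropy and its gradient (backprop)
ann_loss_grad <- function(par, x, y, sizes, decay) {
  wb <- ann_unflatten(par, sizes)
  a <- ann_forward(x, wb$W, wb$b)
  L <- length(wb$W)
  p <- pmin(pmax(a[[L + 1]][, 1], 1e-12), 1 - 1e-12)
  n <- length(y)
  loss <- -sum(y * log(p) + (1 - y) * log(1 - p)) / n + decay * sum(par^2)
  # output delta for logistic + cross-entropy is (p - y)
  delta <- matrix((p - y) / n, n, 1)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(a[[l]], delta) + 2 * decay * wb$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(wb$W[[l]])) * a[[l]] * (1 - a[[l]])
    }
  }
  grad <- numeric(length(par))
  pos <- 0L
  for (l in seq_len(L)) {
    nw <- length(gW[[l]])
    grad[pos + seq_len(nw)] <- gW[[l]]
    pos <- pos + nw
    grad[pos + seq_len(length(gb[[l]]))] <- gb[[l]] + 2 * decay * wb$b[[l]]
    pos <- pos + length(gb[[l]])
  }
  list(loss = loss, grad = grad)
}

ann_fit_scaling <- function(x, method) {
  if (method == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    hi <- ifelse(hi > lo, hi, lo + 1)
    list(method = "minmax", a = lo, b = hi - lo)
  } else {
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    s <- ifelse(s > 0, s, 1)
    list(method = "zscore", a = mu, b = s)
  }
}

ann_apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2, sc$a, "-"), 2, sc$b, "/")
}

#' Train the propensity network
#'
#' Fits the feed-forward classifier on an item-change matrix and a binary
#' response vector. Constant (zero-variance) input columns are dropped
#' before fitting; input scaling parameters are learned on the training data
#' only. Training is deterministic given `spec$seed`; on non-convergence the
#' optimizer is restarted with an incremented seed up to `spec$restarts`
#' times before failing.
#'
#' @param x numeric matrix (subjects x items) of pre-randomization changes.
#' @param y binary vector (1 = placebo responder).
#' @param spec an [ann_spec()].
#' @return an object of class `psw_ann` with the architecture, scaling
#'   parameters, flattened weights, and convergence information.
#' @export
ann_train <- function(x, y, spec) {
  stopifnot(inherits(spec, "ann_spec"))
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (anyNA(x) || anyNA(y)) stop("missing values in training data")
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) stop("all input columns are constant")
  xk <- x[, keep, drop = FALSE]
  sc <- ann_fit_scaling(xk, spec$input_scaling)
  xs <- ann_apply_scaling(xk, sc)
  sizes <- ann_layer_sizes(ncol(xs), spec$hidden)
  npar <- sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])

  fit <- NULL
  # loss and gradient share one backprop pass; cache it across the
  # optimizer's separate fn/gr calls at the same parameter vector
  cache <- new.env(parent = emptyenv())
  eval_lg <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      cache$par <- p
      cache$res <- ann_loss_grad(p, xs, y, sizes, spec$decay)
    }
    cache$res
  }
  for (attempt in 0:spec$restarts) {
    par0 <- with_seed(
      spec$seed + attempt,
      stats::runif(npar, -0.7, 0.7)
    )
    opt <- stats::optim(
      par0,
      fn = function(p) eval_lg(p)$loss,
      gr = function(p) eval_lg(p)$grad,
      method = "BFGS",
      control = list(maxit = spec$max_iterations, reltol = spec$tol)
    )
    if (opt$convergence == 0) {
      fit <- opt
      break
    }
    if (is.null(fit) || opt$value < fit$value) fit <- opt
  }
  if (is.null(fit)) stop("network training failed to converge")
  if (fit$convergence != 0) {
    warning("network training hit the iteration cap after all restarts")
  }
  structure(
    list(
      spec = spec, sizes = sizes, par = fit$par, keep = keep,
      scaling = sc, colnames = colnames(x),
      loss = fit$value, converged = fit$convergence == 0
    ),
    class = "psw_ann"
  )
}

#' @export
print.psw_ann <- function(x, ...) {
  cat(sprintf(
    "<psw_ann> %s net, %d inputs (%d dropped), loss %.4f%s\n",
    paste(x$sizes[-c(1, length(x$sizes))], collapse = "-"),
    sum(x$keep), sum(!x$keep), x$loss,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Predict placebo-response probability
#'
#' @param object a fitted [ann_train()] model.
#' @param newdata numeric matrix with the same columns as the training
#'   matrix.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.psw_ann <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$colnames) && !is.null(colnames(x))) {
    if (!all(object$colnames %in% colnames(x))) {
      stop("newdata is missing training columns")
    }
    x <- x[, object$colnames, drop = FALSE]
  }
  if (ncol(x) != length(object$keep)) stop("newdata has wrong column count")
  xs <- ann_apply_scaling(x[, object$keep, drop = FALSE], object$scaling)
  wb <- ann_unflatten(object$par, object$sizes)
  p <- ann_forward(xs, wb$W, wb$b)[[length(wb$W) + 1]][, 1]
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Persist / restore a propensity model as JSON
#'
#' Writes the architecture, input scaling, dropped columns, weights and the
#' scale name to a plain-text JSON artifact so a run can be reproduced. The
#' stored scale name lets the pipeline refuse to apply a model to data from
#' a different instrument.
#'
#' @param model a [ann_train()] fit.
#' @param path output JSON path.
#' @param scale_name instrument name to stamp into the artifact.
#' @return `ann_to_json()`: `path`, invisibly; `ann_from_json()`: the model.
#' @export
ann_to_json <- function(model, path, scale_name = NA_character_) {
  stopifnot(inherits(model, "psw_ann"))
  obj <- list(
    scale_name = scale_name,
    hidden = model$spec$hidden,
    input_scaling = model$spec$input_scaling,
    decay = model$spec$decay,
    seed = model$spec$seed,
    sizes = model$sizes,
    par = model$par,
    keep = model$keep,
    scaling = model$scaling,
    colnames = model$colnames,
    loss = model$loss,
    converged = model$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ann_to_json
#' @export
ann_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- ann_spec(
    hidden = obj$hidden, seed = obj$seed,
    input_scaling = obj$input_scaling, decay = obj$decay
  )
  model <- structure(
    list(
      spec = spec, sizes = as.integer(obj$sizes), par = as.numeric(obj$par),
      keep = as.logical(obj$keep),
      scaling = list(
        method = obj$scaling$method,
        a = as.numeric(obj$scaling$a), b = as.numeric(obj$scaling$b)
      ),
      colnames = obj$colnames, loss = obj$loss, converged = obj$converged
    ),
    class = "psw_ann"
  )
  attr(model, "scale_name") <- obj$scale_name
  model
}
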