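# One-hidden-layer vertex classifier: PCA-determined hidden size, balanced
# lesional/contralateral training sampling, cross-entropy training, Youden
# thresholding.

logistic <- function(x) 1 / (1 + exp(-x))

#' Hidden-layer size from control-cohort PCA
#'
#' The hidden layer holds as many nodes as the minimum number of principal
#' components of the (mean-centered) control feature matrix needed to
#' explain strictly more than `threshold` of the variance, capped at the
#' matrix rank. This fixes the architecture without exhaustively searching
#' (and overfitting) alternatives.
#'
#' @param control_matrix numeric matrix (rows = control vertices, columns =
#'   features); centered internally.
#' @param threshold explained-variance threshold (default 0.99).
#' @return integer hidden size (>= 1).
#' @export
select_hidden_size <- function(control_matrix, threshold = 0.99) {
  x <- scale(control_matrix, center = TRUE, scale = FALSE)
  d <- svd(x, nu = 0, nv = 0)$d
  ev <- d^2
  rank <- sum(d > max(dim(x)) * .Machine$double.eps * max(d))
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum > threshold)[1]
  if (is.na(k)) k <- rank
  max(1L, min(as.integer(k), rank))
}

#' Assemble a balanced vertex training set
#'
#' For every lesional subject, all vertices inside the manual lesion mask
#' are lesional examples; an equal number of vertices, sampled without
#' replacement from the contralateral (non-lesional) hemisphere, are the
#' healthy examples. Reproducible under `seed`.
#'
#' @param subjects list; each element has `features` (an
#'   asymmetry-augmented `feature_set`) and `mask` (list with `hemisphere`
#'   and `vertices`, 1-based template vertex ids).
#' @param seed integer RNG seed.
#' @return list of class `training_set` with `x` (matrix), `y` (1 =
#'   lesional, 0 = healthy), `subject`, `vertex`, `hemisphere` row
#'   provenance vectors.
#' @export
assemble_training_set <- function(subjects, seed = 1L) {
  rng <- local({set.seed(seed); function(n, k) sample.int(n, k)})
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    hemi <- s$mask$hemisphere
    if (length(hemi) != 1 || !hemi %in% c("left", "right"))
      stop("lesion mask must be unilateral (left or right), got: ",
           paste(hemi, collapse = "/"))
    contra <- setdiff(c("left", "right"), hemi)
    xm <- build_feature_matrix(s$features, hemi)
    xc <- build_feature_matrix(s$features, contra)
    mv <- sort(unique(as.integer(s$mask$vertices)))
    if (length(mv) > nrow(xc))
      stop("lesion mask larger than contralateral hemisphere vertex count")
    hv <- sort(rng(nrow(xc), length(mv)))
    sid <- s$id %||% as.character(i)
    rows[[length(rows) + 1L]] <- list(
      x = rbind(xm[mv, , drop = FALSE], xc[hv, , drop = FALSE]),
      y = rep(c(1L, 0L), each = length(mv)),
      subject = rep(sid, 2L * length(mv)),
      vertex = c(mv, hv),
      hemisphere = rep(c(hemi, contra), each = length(mv)))
  }
  structure(list(
    x = do.call(rbind, lapply(rows, `[[`, "x")),
    y = unlist(lapply(rows, `[[`, "y")),
    subject = unlist(lapply(rows, `[[`, "subject")),
    vertex = unlist(lapply(rows, `[[`, "vertex")),
    hemisphere = unlist(lapply(rows, `[[`, "hemisphere"))),
    class = "training_set")
}

#' Train the one-hidden-layer vertex classifier
#'
#' Logistic hidden and output units, cross-entropy loss, full-batch Adam
#' with an iteration cap; deterministic under `seed` (weight
#' initialization is the only randomness). A model that has not met the
#' gradient tolerance at the cap is returned with `converged = FALSE` and
#' a warning.
#'
#' @param x design matrix (rows = vertices) or a `training_set`.
#' @param y 0/1 labels (ignored when `x` is a `training_set`).
#' @param hidden_size number of hidden nodes (>= 1).
#' @param seed integer RNG seed.
#' @param maxit iteration cap (default 500).
#' @param learning_rate Adam step size.
#' @param tol mean-gradient tolerance for declaring convergence.
#' @return object of class `classifier_model` (weights, biases, input
#'   standardization, `decision_threshold` set later by
#'   [youden_threshold()]).
#' @export
train_network <- function(x, y = NULL, hidden_size, seed = 1L, maxit = 500L,
                          learning_rate = 0.05, tol = 1e-5) {
  if (inherits(x, "training_set")) { y <- x$y; x <- x$x }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("need both classes present for training")
  stopifnot(hidden_size >= 1)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl < 1e-12] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  n <- nrow(xs); p <- ncol(xs); h <- as.integer(hidden_size)
  set.seed(seed)
  w1 <- matrix(stats::runif(p * h, -1, 1) / sqrt(p), p, h)
  b1 <- numeric(h)
  w2 <- matrix(stats::runif(h, -1, 1) / sqrt(h), h, 1)
  b2 <- 0
  theta <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  m <- v <- lapply(theta, function(t) t * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  converged <- FALSE
  for (it in seq_len(maxit)) {
    a1 <- logistic(sweep(xs %*% theta$w1, 2, theta$b1, "+"))
    out <- logistic(as.numeric(a1 %*% theta$w2) + theta$b2)
    delta2 <- (out - y) / n
    delta1 <- outer(delta2, drop(theta$w2)) * a1 * (1 - a1)
    g <- list(
      w1 = crossprod(xs, delta1),
      b1 = colSums(delta1),
      w2 = crossprod(a1, delta2),
      b2 = sum(delta2))
    gnorm <- sqrt(sum(unlist(g)^2))
    if (gnorm < tol) { converged <- TRUE; break }
    for (k in names(theta)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
      mhat <- m[[k]] / (1 - beta1^it)
      vhat <- v[[k]] / (1 - beta2^it)
      theta[[k]] <- theta[[k]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  if (!converged && maxit > 50)
    warning("training reached the iteration cap without meeting the ",
            "gradient tolerance")
  structure(list(w1 = theta$w1, b1 = theta$b1, w2 = theta$w2,
                 b2 = theta$b2, center = ctr, scale = scl,
                 input_dim = p, hidden_size = h,
                 decision_threshold = NA_real_, training_seed = seed,
                 converged = converged, feature_names = colnames(x)),
            class = "classifier_model")
}

#' Per-vertex lesion scores from a trained model
#'
#' @param model a `classifier_model`.
#' @param x design matrix with the training column order.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_vertices <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$input_dim)
    stop(sprintf("design matrix has %d columns; model expects %d",
                 ncol(x), model$input_dim))
  xs <- scale(x, center = model$center, scale = model$scale)
  a1 <- logistic(sweep(xs %*% model$w1, 2, model$b1, "+"))
  as.numeric(logistic(as.numeric(a1 %*% model$w2) + model$b2))
}

#' Youden-index decision threshold
#'
#' Scans a threshold grid; at each candidate `t` a vertex with score
#' `>= t` is called lesional, sensitivity and specificity are computed on
#' the pooled training vertices, and the Youden index
#' `J = sensitivity + specificity - 100` (percent scale) is evaluated. The
#' maximizing threshold is returned; ties break toward the highest
#' threshold (favoring specificity).
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 (or logical) lesional labels.
#' @param grid candidate thresholds (default 0.01 steps over (0, 1)).
#' @return the selected threshold, with the achieved `J` (percent) as
#'   attribute `"youden"`.
#' @export
youden_threshold <- function(scores, labels,
                             grid = seq(0.01, 0.99, by = 0.01)) {
  y <- as.integer(labels > 0)
  if (length(unique(y)) < 2)
    stop("Youden threshold needs both classes present")
  j <- vapply(grid, function(t) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    100 * (sens + spec - 1)
  }, numeric(1))
  best <- max(j)
  t_best <- max(grid[j >= best - 1e-12])
  structure(t_best, youden = best)
}

#' Serialize / restore a classifier model (versioned JSON)
#'
#' @param model a `classifier_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the restored `classifier_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, 1L))
    stop("unsupported model format version")
  obj$format_version <- NULL
  obj$w1 <- matrix(obj$w1, ncol = obj$hidden_size)
  obj$w2 <- matrix(obj$w2, ncol = 1)
  structure(obj, class = "classifier_model")
}
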