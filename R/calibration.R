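#' Dirichlet calibration map
#'
#' The calibration map is `mu(q; W, b) = softmax(W ln q + b)` applied to
#' each predicted probability vector q. The identity parameters (W = I,
#' b = 0) reproduce the inputs exactly.
#'
#' @param W k x k matrix.
#' @param b k-vector.
#' @export
calibration_map <- function(W = diag(N_CLASSES), b = numeric(N_CLASSES)) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), length(b) == nrow(W),
            all(is.finite(W)), all(is.finite(b)))
  structure(list(W = W, b = b, k = nrow(W)), class = "calibration_map")
}

# flatten any probability container to an N x k matrix
prob_matrix <- function(prob_map) {
  if (inherits(prob_map, "probability_map")) {
    p <- prob_map$probs
    k <- dim(p)[3]
    matrix(p, ncol = k)
  } else if (is.matrix(prob_map)) {
    prob_map
  } else {
    stop("expected a probability_map or a matrix", call. = FALSE)
  }
}

#' Apply a Dirichlet calibration map to class probabilities
#'
#' Probabilities are clamped at 1e-12 before the logarithm; outputs are
#' renormalized softmax values so each pixel's vector sums to one.
#'
#' @param cal_map a [calibration_map()].
#' @param prob_map a `probability_map` (or N x k matrix).
#' @return same container type as the input, flagged calibrated.
#' @export
apply_calibration <- function(cal_map, prob_map) {
  q <- prob_matrix(prob_map)
  if (ncol(q) != cal_map$k) {
    stop("class count mismatch between map and probabilities", call. = FALSE)
  }
  z <- log(clamp(q, 1e-12, 1)) %*% t(cal_map$W)
  z <- z + rep(cal_map$b, each = nrow(z))
  out <- softmax_rows(z)
  if (inherits(prob_map, "probability_map")) {
    dim(out) <- dim(prob_map$probs)
    prob_map$probs <- out
    prob_map$calibrated <- TRUE
    prob_map
  } else {
    out
  }
}

# mean multinomial NLL of one-hot targets under the calibrated probabilities
calibration_nll <- function(theta, X, Y) {
  k <- ncol(Y)
  W <- matrix(theta[seq_len(k * k)], k, k)
  b <- theta[k * k + seq_len(k)]
  z <- X %*% t(W)
  z <- z + rep(b, each = nrow(z))
  z <- z - apply(z, 1L, max)
  lse <- log(rowSums(exp(z)))
  -mean(rowSums(Y * z) - lse)
}

calibration_nll_grad <- function(theta, X, Y) {
  k <- ncol(Y)
  W <- matrix(theta[seq_len(k * k)], k, k)
  b <- theta[k * k + seq_len(k)]
  z <- X %*% t(W)
  z <- z + rep(b, each = nrow(z))
  mu <- softmax_rows(z)
  r <- (mu - Y) / nrow(X)
  gW <- crossprod(r, X)         # k x k, rows match W's rows
  gb <- colSums(r)
  c(as.vector(gW), gb)
}

#' Fit Dirichlet calibration on a calibration split
#'
#' Finds (W, b) minimizing the mean multinomial negative log-likelihood of
#' the true classes under `softmax(W ln q + b)`, by BFGS with the analytic
#' gradient, initialized at the identity map. Pixels are treated as
#' independent instances; large splits are subsampled (stratified by true
#' class, seeded). The fit never increases the calibration-split NLL
#' relative to the identity map.
#'
#' @param prob_maps list of `probability_map` objects (or one N x k
#'   matrix) from the calibration split.
#' @param targets matching list of integer class matrices (or one vector),
#'   classes 0..k-1.
#' @param max_pixels subsample cap on fitted pixels.
#' @param seed subsampling seed.
#' @param max_iter BFGS iteration cap.
#' @return a `calibration_map` with fit metadata attached.
#' @export
fit_dirichlet <- function(prob_maps, targets, max_pixels = 2e5, seed = 1L,
                          max_iter = 200L) {
  if (inherits(prob_maps, "probability_map") || is.matrix(prob_maps)) {
    prob_maps <- list(prob_maps)
  }
  if (!is.list(targets)) targets <- list(targets)
  Q <- do.call(rbind, lapply(prob_maps, prob_matrix))
  y <- unlist(lapply(targets, as.integer))
  stopifnot(nrow(Q) == length(y))
  k <- ncol(Q)

  if (nrow(Q) > max_pixels) {
    idx <- with_seed(seed, {
      take <- unlist(lapply(split(seq_along(y), y), function(ii) {
        n_c <- max(1L, round(max_pixels * length(ii) / length(y)))
        ii[sample.int(length(ii), min(n_c, length(ii)))]
      }))
      sort(take)
    })
    Q <- Q[idx, , drop = FALSE]
    y <- y[idx]
  }
  present <- sort(unique(y))
  Y <- matrix(0, nrow(Q), k)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  if (length(present) < k) {
    warning("class(es) absent from the calibration split; ",
            "targets label-smoothed")
    Y <- Y * (1 - 1e-3) + 1e-3 / k
  }
  X <- log(clamp(Q, 1e-12, 1))
  theta0 <- c(as.vector(diag(k)), numeric(k))
  fit <- stats::optim(theta0, fn = calibration_nll, gr = calibration_nll_grad,
                      X = X, Y = Y, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  nll0 <- calibration_nll(theta0, X, Y)
  theta <- if (fit$value <= nll0) fit$par else theta0
  cm <- calibration_map(matrix(theta[seq_len(k * k)], k, k),
                        theta[k * k + seq_len(k)])
  attr(cm, "fit") <- list(nll_identity = nll0,
                          nll_fitted = min(fit$value, nll0),
                          n_pixels = nrow(Q),
                          converged = fit$convergence == 0)
  cm
}

#' Serialize / read a calibration map as JSON
#' @param cal_map a `calibration_map`.
#' @param path file path.
#' @export
write_calibration_json <- function(cal_map, path) {
  jsonlite::write_json(
    list(W = apply(cal_map$W, 1L, function(r) r, simplify = FALSE),
         b = cal_map$b, k = cal_map$k, fit = attr(cal_map, "fit")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(o$W)) o$W else matrix(unlist(o$W), o$k, o$k, byrow = TRUE)
  calibration_map(W, o$b)
}

#' Reliability binning of one-vs-rest class probabilities
#'
#' Bins the predicted probabilities for one class into `m` equal-width
#' ranges (`[0, 1/m), ..., [(m-1)/m, 1]`; the last bin is right-closed) and
#' tabulates per bin the size, the mean predicted probability `s_bar`, and
#' the observed positive fraction `y_bar`. Empty bins carry size 0 and
#' contribute nothing downstream.
#'
#' @param class_probs numeric vector of predicted probabilities for the
#'   class.
#' @param one_vs_rest_labels 0/1 (or logical) vector: instance belongs to
#'   the class.
#' @param m number of bins.
#' @return a `reliability_table` data.frame with columns `bin`, `lower`,
#'   `upper`, `size`, `s_bar`, `y_bar`.
#' @export
reliability_binning <- function(class_probs, one_vs_rest_labels, m = 10L) {
  stopifnot(m >= 1, length(class_probs) == length(one_vs_rest_labels))
  y <- as.numeric(one_vs_rest_labels)
  bin <- pmin(floor(class_probs * m) + 1L, m)  # prob 1.0 -> last bin
  size <- tabulate(bin, nbins = m)
  s_sum <- numeric(m)
  y_sum <- numeric(m)
  agg <- rowsum(cbind(class_probs, y), bin)
  got <- as.integer(rownames(agg))
  s_sum[got] <- agg[, 1L]
  y_sum[got] <- agg[, 2L]
  tab <- data.frame(bin = seq_len(m),
                    lower = (seq_len(m) - 1) / m, upper = seq_len(m) / m,
                    size = size,
                    s_bar = ifelse(size > 0, s_sum / size, NA_real_),
                    y_bar = ifelse(size > 0, y_sum / size, NA_real_))
  attr(tab, "n") <- length(y)
  attr(tab, "m") <- m
  class(tab) <- c("reliability_table", class(tab))
  tab
}

#' Classwise estimated calibration error
#'
#' The mean over classes of the bin-size-weighted absolute gaps between
#' observed positive fraction and mean predicted probability:
#' `(1/k) sum_j sum_i (|B_ij| / N) |y_bar_ij - s_bar_ij|`.
#'
#' @param tables list of `reliability_table`s, one per class, sharing N
#'   and m.
#' @return scalar in \[0, 1\].
#' @export
classwise_ece <- function(tables) {
  ns <- vapply(tables, function(t) attr(t, "n"), numeric(1))
  ms <- vapply(tables, function(t) attr(t, "m"), numeric(1))
  if (length(unique(ns)) != 1L || length(unique(ms)) != 1L) {
    stop("reliability tables must share N and m", call. = FALSE)
  }
  N <- ns[1]
  k <- length(tables)
  per_class <- vapply(tables, function(t) {
    occ <- t$size > 0
    sum(t$size[occ] / N * abs(t$y_bar[occ] - t$s_bar[occ]))
  }, numeric(1))
  sum(per_class) / k
}

#' Classwise ECE of pooled probability maps
#'
#' Convenience wrapper: builds the k one-vs-rest reliability tables from
#' pooled pixels and returns [classwise_ece()].
#' @param prob_maps list of `probability_map`s (or one N x k matrix).
#' @param targets matching integer class containers.
#' @param m bins.
#' @export
pooled_classwise_ece <- function(prob_maps, targets, m = 10L) {
  if (inherits(prob_maps, "probability_map") || is.matrix(prob_maps)) {
    prob_maps <- list(prob_maps)
  }
  if (!is.list(targets)) targets <- list(targets)
  P <- do.call(rbind, lapply(prob_maps, prob_matrix))
  y <- unlist(lapply(targets, as.integer))
  k <- ncol(P)
  tabs <- lapply(seq_len(k) - 1L, function(j) {
    reliability_binning(P[, j + 1L], y == j, m)
  })
  classwise_ece(tabs)
}

#' Plot a reliability diagram to PNG
#' @param table a `reliability_table`.
#' @param path output file.
#' @param class_label plot annotation.
#' @export
plot_reliability_png <- function(table, path, class_label = "") {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  occ <- table$size > 0
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "mean predicted probability",
                 ylab = "observed positive fraction",
                 main = paste("Reliability", class_label))
  graphics::points(table$s_bar[occ], table$y_bar[occ], pch = 19)
  graphics::segments(table$s_bar[occ], table$s_bar[occ],
                     table$s_bar[occ], table$y_bar[occ], col = "red")
  invisible(path)
}
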