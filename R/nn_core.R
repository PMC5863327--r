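#' @include AllClasses.R
NULL

#' Activation functions
#'
#' The four nonlinearities used by the networks, as total elementwise
#' functions: logistic sigmoid \eqn{\sigma(x) = 1 / (1 + e^{-x})},
#' hyperbolic tangent, \eqn{ReLU(x) = \max(0, x)}, and the leaky
#' rectifier \eqn{x \mapsto x} for \eqn{x > 0}, \eqn{\beta x}
#' otherwise, with slope \eqn{\beta \in (0, 1)}. All four are
#' non-decreasing.
#'
#' @param kind one of \code{"sigmoid"}, \code{"tanh"}, \code{"relu"},
#'   \code{"leaky_relu"}.
#' @param x numeric vector or array.
#' @param beta leaky slope, used only for \code{"leaky_relu"}.
#' @return transformed values, same shape as \code{x}.
#' @examples
#' activation("sigmoid", 0)          # 0.5
#' activation("leaky_relu", -1, 0.1) # -0.1
#' @export
activation <- function(kind = c("sigmoid", "tanh", "relu", "leaky_relu"),
                       x, beta = 0.01) {
  kind <- match.arg(kind)
  switch(kind,
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    relu = pmax(0, x),
    leaky_relu = {
      if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
      ifelse(x > 0, x, beta * x)
    })
}

#' Output shape of a same-padded stride-1 convolution
#'
#' With stride 1 and zero padding of \code{(k - 1) / 2} rows/columns per
#' side, an odd-sized kernel preserves the spatial shape: a 32 x 32
#' input convolved with a 3 x 3 kernel yields 32 x 32 feature maps.
#'
#' @param inShape integer \code{c(H, W)}.
#' @param kernel integer \code{c(k1, k2)}, both odd; default 3 x 3.
#' @return integer \code{c(H, W)} (unchanged).
#' @export
convOutputShape <- function(inShape, kernel = c(3L, 3L)) {
  if (any(kernel %% 2L == 0L)) stop("kernel dimensions must be odd")
  if (any(inShape < 1L)) stop("input shape must be positive")
  as.integer(inShape)
}

#' Output shape of 2 x 2 pooling
#'
#' Non-overlapping 2 x 2 pooling halves each spatial dimension
#' (32 x 32 -> 16 x 16). Odd dimensions are an error; the architectures
#' in this package never produce one.
#'
#' @param inShape integer \code{c(H, W)}, both even.
#' @return integer \code{c(H / 2, W / 2)}.
#' @export
poolOutputShape <- function(inShape) {
  if (any(inShape %% 2L != 0L))
    stop("pooling requires even spatial dimensions; got ",
         paste(inShape, collapse = " x "))
  as.integer(inShape / 2L)
}

#' Trainable parameter count of an LSTM layer
#'
#' An LSTM with input dimension \code{d} and \code{h} hidden units has
#' four gate blocks (input gate, candidate, forget gate, output gate),
#' each with an \code{h x d} input weight matrix, an \code{h x h}
#' recurrent matrix and an \code{h} bias: \code{4 * (h * (d + h) + h)}
#' parameters in total.
#'
#' @param d input dimension per time step (>= 1).
#' @param h hidden units (>= 1).
#' @return integer parameter count.
#' @examples
#' lstmParamCount(128, 42)  # 28728
#' @export
lstmParamCount <- function(d, h) {
  if (d < 1L || h < 1L) stop("d and h must be >= 1")
  as.integer(4 * (h * (d + h) + h))
}

#' Trainable parameter count of a dense layer
#'
#' \code{in * out} weights plus \code{out} biases.
#'
#' @param inUnits,outUnits positive unit counts.
#' @return integer parameter count.
#' @export
denseParamCount <- function(inUnits, outUnits) {
  if (inUnits < 1L || outUnits < 1L) stop("unit counts must be >= 1")
  as.integer(inUnits * outUnits + outUnits)
}

#' Softmax probabilities and cross-entropy loss
#'
#' Converts a pair (or any vector) of end-layer scores into class
#' probabilities \eqn{\bar y_k = \exp(F_k) / \sum_j \exp(F_j)} and
#' returns the cross-entropy loss \eqn{-\ln \bar y_k} of the true
#' class, stabilized by log-sum-exp so arbitrarily large scores never
#' overflow. The predicted label is the argmax of the probabilities
#' (ties break to the lower index, i.e. benign).
#'
#' @param scores numeric vector of end-layer scores (class 1 = benign,
#'   class 2 = malignant).
#' @param trueClass integer index of the true class.
#' @return list with \code{probs} (sums to 1), \code{loss} (>= 0) and
#'   \code{predicted} (integer argmax index).
#' @examples
#' softmaxLoss(c(0, 0), 1)$loss  # log(2)
#' @export
softmaxLoss <- function(scores, trueClass) {
  stopifnot(all(is.finite(scores)), trueClass >= 1L,
            trueClass <= length(scores))
  m <- max(scores)
  lse <- m + log(sum(exp(scores - m)))
  logp <- scores - lse
  list(probs = exp(logp), loss = -logp[trueClass],
       predicted = which.max(logp))
}

#' Soft-margin SVM objective
#'
#' Evaluates the primal soft-margin objective
#' \deqn{\frac{1}{2} \|W\|^2 + C \sum_i \max(0, 1 - y_i (\langle W, x_i\rangle + b))}
#' for a linear decision function with labels \eqn{y_i \in \{-1, +1\}}.
#' At \code{W = 0, b = 0} every slack is 1 and the objective equals
#' \code{C * n}; on data separated with margins >= 1 the slack term
#' vanishes and the objective is \eqn{\|W\|^2 / 2}.
#'
#' @param W numeric weight vector.
#' @param X numeric matrix (n x length(W)) of feature rows.
#' @param y labels in \{-1, +1\}.
#' @param C penalty parameter (> 0).
#' @param b intercept (default 0, matching the homogeneous form).
#' @return objective value (scalar).
#' @examples
#' svmObjective(0.5, matrix(c(-2, 2), 2, 1), c(-1, 1), C = 1)  # 0.125
#' @export
svmObjective <- function(W, X, y, C = 1, b = 0) {
  X <- as.matrix(X)
  if (ncol(X) != length(W))
    stop("dimension mismatch: ncol(X) = ", ncol(X), ", length(W) = ",
         length(W))
  if (nrow(X) != length(y)) stop("X and y disagree in length")
  if (!(C > 0)) stop("C must be > 0")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 / +1")
  margins <- y * (as.vector(X %*% W) + b)
  0.5 * sum(W * W) + C * sum(pmax(0, 1 - margins))
}
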