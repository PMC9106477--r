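#' Gaussian basis (membership) function
#'
#' \eqn{\varphi(v) = \exp(-\|v - c\|^2 / (2\sigma^2))}, in (0, 1]; equal to 1
#' exactly when \code{v == center}, and symmetric under swapping \code{v}
#' and \code{center}.
#'
#' @param v numeric vector.
#' @param center numeric vector of the same length.
#' @param sigma positive width.
#' @return Scalar in (0, 1].
#' @examples
#' gaussianBasis(1, 1, 2)            # 1
#' gaussianBasis(c(1, 1), c(0, 0), 1) # exp(-1)
#' @export
gaussianBasis <- function(v, center, sigma) {
  if (sigma <= 0) stop("gaussianBasis: sigma must be positive")
  exp(-sum((as.numeric(v) - as.numeric(center))^2) / (2 * sigma^2))
}

#' RBF head forward pass
#'
#' \eqn{f(v) = \sum_i w_i \varphi(\|v - C_i\|)}: the Gaussian-basis mapping
#' the training head fits; linear in the weights.
#'
#' @param v input vector.
#' @param weights numeric vector, one weight per unit.
#' @param centers matrix with one center per row (length(v) columns), or a
#'   vector for scalar inputs.
#' @param sigma positive width shared by the units.
#' @return Scalar response.
#' @export
rbfForward <- function(v, weights, centers, sigma) {
  centers <- if (is.null(dim(centers))) matrix(centers, ncol = length(v))
             else as.matrix(centers)
  if (length(weights) != nrow(centers))
    stop("rbfForward: need one weight per center")
  phi <- vapply(seq_len(nrow(centers)),
                function(i) gaussianBasis(v, centers[i, ], sigma), numeric(1))
  sum(weights * phi)
}

# Design matrix of the RBF head: Phi[i, j] = phi(||v_i - C_j||).
rbfDesign <- function(V, centers, sigma) {
  V <- as.matrix(V); centers <- as.matrix(centers)
  P <- nrow(V); n <- nrow(centers)
  out <- matrix(0, P, n)
  for (j in seq_len(n))
    out[, j] <- exp(-rowSums(sweep(V, 2L, centers[j, ])^2) / (2 * sigma^2))
  out
}

#' Training residuals and total error
#'
#' \eqn{e_i = t_i - y_i} and \eqn{E = \frac{1}{2}\sum_i |e_i|^2}, the
#' stopping quantity of gradient-descent training. Invariant under sample
#' permutation.
#'
#' @param targets,outputs numeric vectors of equal length.
#' @return List with \code{residuals} and \code{E}.
#' @examples
#' trainingError(c(3, 4), c(0, 0))$E  # 12.5
#' @export
trainingError <- function(targets, outputs) {
  if (length(targets) != length(outputs))
    stop("trainingError: lengths differ")
  e <- targets - outputs
  list(residuals = e, E = 0.5 * sum(abs(e)^2))
}

# Analytic gradient of E with respect to the RBF head weights:
# dE/dw_j = -sum_i e_i * phi_ij.
rbfWeightGradient <- function(weights, V, targets, centers, sigma) {
  Phi <- rbfDesign(V, centers, sigma)
  y <- drop(Phi %*% weights)
  e <- targets - y
  -drop(crossprod(Phi, e))
}

#' One gradient-descent step on the RBF head
#'
#' Moves the head weights along \eqn{-\nabla E} for the batch. The head is
#' linear in its weights, so for a sufficiently small learning rate E is
#' non-increasing.
#'
#' @param params list with \code{weights}, \code{centers} (matrix, one row
#'   per unit) and \code{sigma}.
#' @param batch list with \code{inputs} (matrix, one sample per row) and
#'   \code{targets}.
#' @param lr positive learning rate.
#' @return Updated \code{params}.
#' @export
gradientStep <- function(params, batch, lr) {
  if (lr <= 0) stop("gradientStep: lr must be positive")
  g <- rbfWeightGradient(params$weights, batch$inputs, batch$targets,
                         params$centers, params$sigma)
  if (!all(is.finite(g)))
    stop("gradientStep: non-finite gradient (weights = ",
         paste(signif(params$weights, 3), collapse = ", "), ")")
  params$weights <- params$weights - lr * g
  params
}

#' Fuzzy fusion layer
#'
#' \eqn{x = \tanh(w_d y_d + w_f y_f + b)}: the affine combination of the
#' deep-branch output \code{yd} and the fuzzy-branch output \code{yf},
#' passed through the hyperbolic-tangent transfer; output in (-1, 1).
#' With \code{wf = 0} the layer reduces to a plain CNN activation.
#'
#' @param yd,yf numeric arrays of identical shape.
#' @param params list with scalars \code{wd}, \code{wf}, \code{b}.
#' @return Array of fused activations.
#' @examples
#' fuzzyFusionForward(1, 2, list(wd = 0.5, wf = 0.25, b = 0))  # tanh(1)
#' @export
fuzzyFusionForward <- function(yd, yf, params) {
  if (!identical(dim(yd), dim(yf)) || length(yd) != length(yf))
    stop("fuzzyFusionForward: yd and yf must have the same shape")
  tanh(params$wd * yd + params$wf * yf + params$b)
}

#' Max pooling of a window
#'
#' @param window non-empty numeric vector of activations.
#' @return The window maximum.
#' @export
maxPool <- function(window) {
  if (length(window) == 0L) stop("maxPool: empty window")
  max(window)
}

#' Stochastic pooling of a window
#'
#' In training mode, samples one window element with probability
#' proportional to its activation; in inference mode returns the
#' probability-weighted average \eqn{\sum_i p_i a_i}. Negative activations
#' are shifted to non-negative before forming the probabilities (the
#' returned values are the originals); an all-equal window returns that
#' value under both modes.
#'
#' @param window non-empty numeric vector.
#' @param mode \code{"inference"} (default) or \code{"training"}.
#' @return Scalar pooled value.
#' @examples
#' stochasticPool(c(1, 1, 3, 3))  # (1*1 + 1*1 + 3*3 + 3*3) / 8 = 2.5
#' @export
stochasticPool <- function(window, mode = c("inference", "training")) {
  mode <- match.arg(mode)
  if (length(window) == 0L) stop("stochasticPool: empty window")
  w <- as.numeric(window)
  shifted <- if (min(w) < 0) w - min(w) else w
  s <- sum(shifted)
  p <- if (s <= 0) rep(1 / length(w), length(w)) else shifted / s
  if (mode == "inference") sum(p * w) else w[sample.int(length(w), 1L, prob = p)]
}

#' FDCNet architecture configuration
#'
#' The architecture constants of the fuzzy deep convolutional network:
#' a 20-channel dilated (atrous) convolution with a 3x3 filter (3x3x3 for
#' volumes) at rate 3, a 10-unit Gaussian fuzzy layer whose mixing window is
#' dilated at rate 7, dual pooling (stochastic + max) over windows dilated
#' at rate 11, and a fully connected softmax head over the configured
#' classes.
#'
#' @param convChannels number of convolution channels (default 20).
#' @param filterSize per-axis filter size (default 3).
#' @param rateConv,rateFuzzy,ratePool dilation rates (defaults 3, 7, 11).
#' @param fuzzyUnits Gaussian membership units (default 10).
#' @param pooling character vector of pooling modes used side by side.
#' @param poolLayers number of pooling layers carried by the layer-search
#'   plane (2 to 5; default 2).
#' @param nClasses output classes (default 3: benign, malignant, suspicious).
#' @param inputShape integer image shape, e.g. \code{c(32, 32)}.
#' @return A list of class \code{"FDCNetConfig"}.
#' @export
fdcnetConfig <- function(convChannels = 20L, filterSize = 3L, rateConv = 3L,
                         rateFuzzy = 7L, ratePool = 11L, fuzzyUnits = 10L,
                         pooling = c("stochastic", "max"), poolLayers = 2L,
                         nClasses = 3L, inputShape = c(32L, 32L)) {
  stopifnot(rateConv >= 1, rateFuzzy >= 1, ratePool >= 1,
            fuzzyUnits >= 1, nClasses >= 2, convChannels >= 1,
            filterSize %% 2 == 1, poolLayers >= 2, poolLayers <= 5)
  structure(list(convChannels = as.integer(convChannels),
                 filterSize = as.integer(filterSize),
                 rateConv = as.integer(rateConv),
                 rateFuzzy = as.integer(rateFuzzy),
                 ratePool = as.integer(ratePool),
                 fuzzyUnits = as.integer(fuzzyUnits),
                 pooling = pooling, poolLayers = as.integer(poolLayers),
                 nClasses = as.integer(nClasses),
                 inputShape = as.integer(inputShape)),
            class = "FDCNetConfig")
}

# Minimum input side so that every dilated 3-tap window fits.
fdcnetMinInput <- function(config) {
  r <- max(config$rateConv, config$rateFuzzy, config$ratePool)
  (config$filterSize - 1L) * r + 1L
}

#' Build an FDCNet model
#'
#' Initializes the feature layers (dilated convolution filters, fuzzy
#' centers/widths and mixing weights, fusion parameters) from the given
#' seed. The fully connected head is attached by [trainFDCNet()]. With
#' \code{fuzzy = FALSE} the fusion weight \code{wf} is set to 0 so the
#' network is an identically-seeded plain dilated CNN.
#'
#' @param config an [fdcnetConfig()].
#' @param seed integer seed for the parameter draw.
#' @param fuzzy include the fuzzy branch (default TRUE).
#' @return A list of class \code{"FDCNetModel"}.
#' @export
buildNetwork <- function(config, seed = 1L, fuzzy = TRUE) {
  stopifnot(inherits(config, "FDCNetConfig"))
  minSide <- fdcnetMinInput(config)
  if (any(config$inputShape < minSide))
    stop("input shape ", paste(config$inputShape, collapse = "x"),
         " is smaller than the dilated receptive field; minimum side is ",
         minSide)
  nd <- length(config$inputShape)
  K <- config$filterSize^nd
  cc <- config$convChannels
  params <- withSeed(seed, {
    Wc <- matrix(stats::rnorm(K * cc, sd = 1 / sqrt(K)), K, cc)
    Wc <- sweep(Wc, 2L, colMeans(Wc))   # zero-mean (bandpass) filters
    list(Wc = Wc,
         bc = stats::rnorm(cc, sd = 0.1),
         mix = stats::rnorm(K, sd = 1 / K) + 1 / K,
         centers = matrix(stats::rnorm(config$fuzzyUnits * cc, sd = 0.5),
                          config$fuzzyUnits, cc),
         widths = rep(1, config$fuzzyUnits),
         Mf = matrix(stats::rnorm(config$fuzzyUnits * cc,
                                  sd = 1 / sqrt(config$fuzzyUnits)),
                     config$fuzzyUnits, cc),
         wd = 1, wf = if (fuzzy) 0.5 else 0, b = 0)
  })
  structure(list(config = config, params = params, seed = as.integer(seed),
                 fc = NULL, scaler = NULL, eigenModel = NULL,
                 classes = NULL),
            class = "FDCNetModel")
}

#' @export
print.FDCNetModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "FDCNetModel: %s input, %d-channel conv (rate %d), %d fuzzy units ",
    "(rate %d), pooling %s (rate %d), %d classes%s\n"),
    paste(cfg$inputShape, collapse = "x"), cfg$convChannels, cfg$rateConv,
    cfg$fuzzyUnits, cfg$rateFuzzy, paste(cfg$pooling, collapse = "+"),
    cfg$ratePool, cfg$nClasses,
    if (is.null(x$fc)) " (head untrained)" else " (trained)"))
  cat(sprintf("  parameters: %d\n", parameterCount(x)))
  invisible(x)
}

#' Deterministic parameter count
#'
#' Layer-by-layer sum of the model's parameters: convolution filters and
#' biases, fuzzy centers, widths and mixing matrix, the three fusion
#' scalars, and (when trained) the fully connected head.
#'
#' @param model an [buildNetwork()] model.
#' @return Integer parameter count.
#' @export
parameterCount <- function(model) {
  cfg <- model$config
  nd <- length(cfg$inputShape)
  K <- cfg$filterSize^nd
  n <- K * cfg$convChannels + cfg$convChannels +       # conv filters + bias
       K +                                             # deep mixing window
       cfg$fuzzyUnits * cfg$convChannels +             # fuzzy centers
       cfg$fuzzyUnits +                                # fuzzy widths
       cfg$fuzzyUnits * cfg$convChannels +             # fuzzy mixing
       3L                                              # wd, wf, b
  if (!is.null(model$fc)) n <- n + length(model$fc$W) + length(model$fc$b)
  as.integer(n)
}

# Neighbor index maps for a dilated 3^nd window with reflect padding.
dilatedIndexMaps <- function(d, rate, filterSize = 3L) {
  r <- (filterSize - 1L) %/% 2L
  offs <- as.matrix(do.call(expand.grid, rep(list((-r:r) * rate), length(d))))
  lapply(seq_len(nrow(offs)), function(i) reflectShiftIndex(d, offs[i, ]))
}

# Dilated 3^nd convolution of a single-channel array: returns npix x K
# matrix of tapped neighbor values.
im2row <- function(a, idxMaps) {
  vapply(idxMaps, function(ix) a[ix], numeric(length(a)))
}

#' FDCNet feature maps and pooled feature vector
#'
#' Runs the feature layers on one image: dilated convolution (tanh), the
#' deep mixing branch and the fuzzy membership branch, fuzzy fusion, and
#' dual pooling — for every channel, the maximum over all valid dilated
#' 3x3 (3x3x3) window positions (max pooling) and the activation-weighted
#' stochastic pool over the same region. With \code{useFuzzy = FALSE} the
#' fuzzy branch is skipped entirely (the plain CNN path).
#'
#' @param model an [buildNetwork()] model.
#' @param image [RawImage-class] or numeric array matching the configured
#'   input shape.
#' @param useFuzzy evaluate the fuzzy branch (default TRUE).
#' @param poolMode \code{"inference"} (deterministic) or \code{"training"}.
#' @return Numeric feature vector (one value per channel and pooling mode).
#' @export
fdcnetFeatures <- function(model, image, useFuzzy = TRUE,
                           poolMode = "inference") {
  cfg <- model$config
  a <- asImageArray(image)
  if (!identical(as.integer(dim(a)), cfg$inputShape))
    stop("fdcnetFeatures: image shape ", paste(dim(a), collapse = "x"),
         " does not match configured input shape ",
         paste(cfg$inputShape, collapse = "x"))
  mx <- if (is(image, "RawImage")) maxValue(image) else max(1, max(a))
  x <- a / mx
  d <- dim(x)
  p <- model$params
  convIdx <- dilatedIndexMaps(d, cfg$rateConv, cfg$filterSize)
  convAct <- tanh(sweep(im2row(x, convIdx) %*% p$Wc, 2L, p$bc, `+`))
  mixIdx <- dilatedIndexMaps(d, cfg$rateFuzzy, cfg$filterSize)
  yd <- matrix(0, nrow(convAct), ncol(convAct))
  for (k in seq_along(mixIdx))
    yd <- yd + p$mix[k] * convAct[mixIdx[[k]], , drop = FALSE]
  if (useFuzzy && p$wf != 0) {
    phi <- matrix(0, nrow(convAct), cfg$fuzzyUnits)
    for (j in seq_len(cfg$fuzzyUnits))
      phi[, j] <- exp(-rowSums(sweep(convAct, 2L, p$centers[j, ])^2) /
                        (2 * p$widths[j]^2))
    yf <- phi %*% p$Mf
    fused <- fuzzyFusionForward(yd, yf, list(wd = p$wd, wf = p$wf, b = p$b))
  } else {
    fused <- tanh(p$wd * yd + p$b)
  }
  poolFeatures(fused, d, cfg, poolMode)
}

# Dual pooling with channel-level aggregation: windows of a dilated 3^nd
# footprint tile the valid interior; their union covers it, so max pooling
# aggregates to the per-channel interior maximum, and stochastic pooling
# is applied per channel over the same region.
poolFeatures <- function(fused, d, cfg, poolMode) {
  rate <- cfg$ratePool
  inner <- lapply(d, function(n) seq(rate + 1, n - rate))
  g <- as.matrix(do.call(expand.grid, inner))
  mult <- cumprod(c(1, d[-length(d)]))
  lin <- as.integer(1 + (g - 1) %*% mult)
  region <- fused[lin, , drop = FALSE]
  out <- numeric(0)
  for (mode in cfg$pooling) {
    out <- c(out, if (mode == "max") apply(region, 2L, max)
                  else apply(region, 2L, stochasticPool, mode = poolMode))
  }
  out
}

#' Maximum connected-layer amplitude
#'
#' \eqn{\alpha \times (n_{current}/n_{total}) \times (var_{high} -
#' var_{low})}: the cap on the connected-layer budget used by
#' [layerSearch()]. Linear (homogeneous) in \code{alpha}.
#'
#' @param alpha scale variable.
#' @param nCurrent,nTotal current and total layer counts; \code{nTotal > 0}.
#' @param varHigh,varLow search-variable bounds, \code{varHigh > varLow}.
#' @return Scalar amplitude.
#' @examples
#' maxConnectedLayer(2, 1, 2, 10, 0)  # 10
#' @export
maxConnectedLayer <- function(alpha, nCurrent, nTotal, varHigh, varLow) {
  stopifnot(nTotal > 0, varHigh > varLow)
  alpha * (nCurrent / nTotal) * (varHigh - varLow)
}

#' Regularized bilinear objective J
#'
#' \eqn{J = \frac{1}{2}\sum_{(i,j): r_{ij}=1}(\theta_j^T x_i - y_{ij})^2 +
#' \frac{\lambda}{2}(\sum_i \|x_i\|^2 + \sum_j \|\theta_j\|^2)}: the
#' overall goal function minimized by the layer search (its profit is
#' \code{-J}).
#'
#' @param X n_m x k matrix (rows \eqn{x_i}).
#' @param Theta n_u x k matrix (rows \eqn{\theta_j}).
#' @param Y n_m x n_u target matrix.
#' @param R n_m x n_u 0/1 observation mask.
#' @param lambda non-negative regularizer.
#' @return Scalar J.
#' @export
objectiveJ <- function(X, Theta, Y, R, lambda) {
  stopifnot(lambda >= 0)
  X <- as.matrix(X); Theta <- as.matrix(Theta)
  Err <- (X %*% t(Theta) - Y) * R
  0.5 * sum(Err^2) + lambda / 2 * (sum(X^2) + sum(Theta^2))
}

#' Analytic gradient of [objectiveJ()]
#'
#' @inheritParams objectiveJ
#' @return List with \code{dX} and \code{dTheta}.
#' @export
objectiveJGradient <- function(X, Theta, Y, R, lambda) {
  X <- as.matrix(X); Theta <- as.matrix(Theta)
  Err <- (X %*% t(Theta) - Y) * R
  list(dX = Err %*% Theta + lambda * X,
       dTheta = t(Err) %*% X + lambda * Theta)
}

#' Profit of a candidate configuration
#'
#' The degree of suitability of a candidate: the evaluation function's value,
#' negated when it is a cost (\code{profit = -J}); maximizing profit
#' minimizes the objective.
#'
#' @param candidate candidate description passed to \code{evalFn}.
#' @param evalFn function(candidate) returning a cost (J-like) value.
#' @return Scalar profit.
#' @export
profitValue <- function(candidate, evalFn) {
  -evalFn(candidate)
}

#' Layer-search configuration
#'
#' @param alpha amplitude scale of [maxConnectedLayer()] (default 1).
#' @param varHigh,varLow bounds of the connected-layer budget (defaults 10, 1).
#' @param poolRange allowed pooling-layer counts, within \code{[2, 5]}.
#' @param nCandidates candidate population size (default 20).
#' @param nIter search iterations (default 5).
#' @param lambda regularizer passed through to J-style evaluators.
#' @param exploreFraction fraction l of the distance to the best candidate
#'   traversed per iteration (default 0.5).
#' @param deviation angular deviation bound phi in radians (default pi/6).
#' @param seed RNG seed.
#' @return A list of class \code{"LayerSearchConfig"}.
#' @export
layerSearchConfig <- function(alpha = 1, varHigh = 10, varLow = 1,
                              poolRange = c(2L, 5L), nCandidates = 20L,
                              nIter = 5L, lambda = 0.1,
                              exploreFraction = 0.5, deviation = pi / 6,
                              seed = 1L) {
  stopifnot(varHigh > varLow, poolRange[1] >= 2, poolRange[2] <= 5,
            exploreFraction >= 0, exploreFraction <= 1, nCandidates >= 0)
  structure(list(alpha = alpha, varHigh = varHigh, varLow = varLow,
                 poolRange = as.integer(poolRange),
                 nCandidates = as.integer(nCandidates),
                 nIter = as.integer(nIter), lambda = lambda,
                 exploreFraction = exploreFraction, deviation = deviation,
                 seed = as.integer(seed)),
            class = "LayerSearchConfig")
}

#' Search the layer-configuration plane
#'
#' Samples \code{nCandidates} candidate configurations with pooling-layer
#' counts uniform on the configured range and connected-layer budgets
#' uniform between the bounds (capped by [maxConnectedLayer()]). Each
#' iteration moves every candidate a fraction \code{exploreFraction} of the
#' way toward the current best in the 2D (pool-count, budget) plane, with
#' the step direction perturbed by an angle drawn within \code{±deviation};
#' profit is \code{-evalFn(candidate)}. Deterministic under the configured
#' seed.
#'
#' @param search a [layerSearchConfig()].
#' @param evalFn function(candidate) returning a cost, where a candidate is
#'   a list with \code{poolCount} and \code{budget}.
#' @return A list of class \code{"LayerSearchResult"}: the winning
#'   \code{candidate}, its \code{profit}, the final \code{population}, and
#'   an [fdcnetConfig()] with the chosen pooling-layer count.
#' @export
layerSearch <- function(search, evalFn) {
  stopifnot(inherits(search, "LayerSearchConfig"))
  if (search$nCandidates < 1L) stop("layerSearch: need at least one candidate")
  withSeed(search$seed, {
    n <- search$nCandidates
    pool <- sample(seq(search$poolRange[1], search$poolRange[2]), n,
                   replace = TRUE)
    budget <- stats::runif(n, search$varLow, search$varHigh)
    capFor <- function(pc) {
      cap <- maxConnectedLayer(search$alpha, pc, search$poolRange[2],
                               search$varHigh, search$varLow)
      max(search$varLow, min(search$varHigh, cap))
    }
    budget <- pmin(budget, vapply(pool, capFor, numeric(1)))
    evalAll <- function() vapply(seq_len(n), function(i)
      profitValue(list(poolCount = pool[i], budget = budget[i]), evalFn),
      numeric(1))
    prof <- evalAll()
    for (it in seq_len(search$nIter)) {
      best <- which.max(prof)
      for (i in seq_len(n)[-best]) {
        dx <- pool[best] - pool[i]
        dy <- budget[best] - budget[i]
        ang <- stats::runif(1, -search$deviation, search$deviation)
        step <- search$exploreFraction *
          c(cos(ang) * dx - sin(ang) * dy, sin(ang) * dx + cos(ang) * dy)
        pool[i] <- min(search$poolRange[2],
                       max(search$poolRange[1], round(pool[i] + step[1])))
        budget[i] <- min(capFor(pool[i]),
                         max(search$varLow, budget[i] + step[2]))
      }
      prof <- evalAll()
    }
    best <- which.max(prof)
    structure(list(
      candidate = list(poolCount = pool[best], budget = budget[best]),
      profit = prof[best],
      population = data.frame(poolCount = pool, budget = budget,
                              profit = prof),
      config = fdcnetConfig(poolLayers = pool[best])),
      class = "LayerSearchResult")
  })
}

#' @export
print.LayerSearchResult <- function(x, ...) {
  cat(sprintf("LayerSearchResult: pool layers %d, budget %.3g, profit %.4g\n",
              x$candidate$poolCount, x$candidate$budget, x$profit))
  invisible(x)
}

#' Training configuration
#'
#' @param learningRate gradient-descent step size (default 1).
#' @param epochs maximum epochs (default 600).
#' @param trainFraction fraction of samples in the training split (0.7).
#' @param lossThreshold stop when the per-epoch error E drops below this
#'   (default 0: run all epochs).
#' @param seed RNG seed for the stratified split.
#' @param eigenF retained eigen dimension used by the classifier
#'   (default 4; \code{NULL} falls back to the variance rule of
#'   [trainEigenModel()]).
#' @param ridge small L2 penalty on the head weights (default 1e-3).
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learningRate = 1, epochs = 600L, trainFraction = 0.7,
                        lossThreshold = 0, seed = 42L, eigenF = 4L,
                        ridge = 1e-3) {
  stopifnot(learningRate > 0, trainFraction > 0, trainFraction < 1)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 trainFraction = trainFraction,
                 lossThreshold = lossThreshold, seed = as.integer(seed),
                 eigenF = eigenF, ridge = ridge),
            class = "TrainConfig")
}

#' Stratified train/test split
#'
#' Deterministic under \code{seed}; per-class proportions follow
#' \code{trainFraction}; the two index sets partition the samples.
#'
#' @param labels vector of class labels.
#' @param trainFraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return List with integer vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.7, seed = 42L) {
  labels <- as.character(labels)
  withSeed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      k <- max(1L, round(length(idx) * trainFraction))
      train <- c(train, sort(sample(idx, k)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# Feature matrix (samples x features) for a dataset: pooled FDCNet
# activations, morphological segmentation descriptors, and eigen-space
# projections, concatenated per image.
datasetFeatures <- function(model, images, eigenModel) {
  feats <- lapply(images, function(im) {
    cnn <- fdcnetFeatures(model, im)
    seg <- segmentationDescriptors(im)
    eig <- projectImage(as.numeric(asImageArray(im)), eigenModel)
    c(cnn, seg, eig)
  })
  do.call(rbind, feats)
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the FDCNet classifier
#'
#' Performs a stratified 70/30 split (seeded), trains an eigenimage model on
#' the training images, extracts pooled FDCNet features concatenated with
#' the eigen projections, standardizes them, and fits the fully connected
#' softmax head by batch gradient descent. Training stops at the epoch
#' limit or as soon as the epoch error \eqn{E = \frac{1}{2}\sum|e_i|^2}
#' (residuals against the one-hot targets) drops below
#' \code{lossThreshold}.
#'
#' @param model an [buildNetwork()] model (head untrained).
#' @param dataset list of samples, each with \code{$image} (a
#'   [RawImage-class]) and \code{$label}.
#' @param cfg a [trainConfig()].
#' @return The trained model, with \code{$history} (per-epoch E and
#'   cross-entropy), \code{$split}, \code{$eigenModel}, \code{$fc},
#'   \code{$scaler} and \code{$classes} filled in.
#' @export
trainFDCNet <- function(model, dataset, cfg = trainConfig()) {
  stopifnot(inherits(model, "FDCNetModel"), inherits(cfg, "TrainConfig"))
  labels <- vapply(dataset, function(s) as.character(s$label), character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("trainFDCNet: need at least two classes, got ", length(classes))
  split <- stratifiedSplit(labels, cfg$trainFraction, cfg$seed)
  trainImgs <- lapply(dataset[split$train], `[[`, "image")
  Xflat <- vapply(trainImgs, function(im) as.numeric(asImageArray(im)),
                  numeric(length(asImageArray(dataset[[1]]$image))))
  eigenModel <- trainEigenModel(Xflat, f = cfg$eigenF)
  Ftr <- datasetFeatures(model, trainImgs, eigenModel)
  mu <- colMeans(Ftr)
  sdv <- apply(Ftr, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Ztr <- scale(Ftr, center = mu, scale = sdv)
  y <- match(labels[split$train], classes)
  Tm <- matrix(0, length(y), length(classes))
  Tm[cbind(seq_along(y), y)] <- 1
  W <- matrix(0, ncol(Ztr), length(classes))
  b <- rep(0, length(classes))
  n <- nrow(Ztr)
  histE <- numeric(0); histCE <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    P <- softmaxRows(sweep(Ztr %*% W, 2L, b, `+`))
    err <- trainingError(as.numeric(Tm), as.numeric(P))
    ce <- -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
    histE <- c(histE, err$E); histCE <- c(histCE, ce)
    if (err$E < cfg$lossThreshold) break
    G <- (P - Tm) / n
    W <- W - cfg$learningRate * (crossprod(Ztr, G) + cfg$ridge * W)
    b <- b - cfg$learningRate * colSums(G)
  }
  model$fc <- list(W = W, b = b)
  model$scaler <- list(center = mu, scale = sdv)
  model$eigenModel <- eigenModel
  model$classes <- classes
  model$history <- data.frame(epoch = seq_along(histE), E = histE,
                              crossEntropy = histCE)
  model$split <- split
  model
}

#' Classify an image with a trained FDCNet
#'
#' Extracts the pooled FDCNet features and eigen projection, applies the
#' stored standardization and softmax head, and returns the argmax label
#' (ties broken toward the lowest class index) with per-class scores
#' summing to 1.
#'
#' @param model a trained [trainFDCNet()] model.
#' @param image a [RawImage-class] or array.
#' @return List with \code{label} and named \code{scores}.
#' @export
predictFDCNet <- function(model, image) {
  if (is.null(model$fc)) stop("predictFDCNet: model head is untrained")
  f <- c(fdcnetFeatures(model, image),
         segmentationDescriptors(image),
         projectImage(as.numeric(asImageArray(image)), model$eigenModel))
  z <- (f - model$scaler$center) / model$scaler$scale
  s <- drop(z %*% model$fc$W) + model$fc$b
  p <- exp(s - max(s)); p <- p / sum(p)
  names(p) <- model$classes
  list(label = model$classes[which.max(p)], scores = p)
}

#' Classify many images
#'
#' @param model a trained model.
#' @param images list of images.
#' @return List with character \code{labels} and a score matrix
#'   \code{scores} (one row per image).
#' @export
predictFDCNetBatch <- function(model, images) {
  res <- lapply(images, predictFDCNet, model = model)
  list(labels = vapply(res, `[[`, character(1), "label"),
       scores = do.call(rbind, lapply(res, `[[`, "scores")))
}

#' Save an FDCNet model as a plain-text archive
#'
#' Writes the configuration and head as JSON, parameter matrices as CSV,
#' and the eigen model via [saveEigenModel()]; [loadFDCNetModel()] restores
#' a model that predicts identically.
#'
#' @param model a (trained or untrained) \code{FDCNetModel}.
#' @param dir destination directory.
#' @return \code{dir}, invisibly.
#' @export
saveFDCNetModel <- function(model, dir) {
  stopifnot(inherits(model, "FDCNetModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.csv(as.data.frame(m),
                                        file.path(dir, f), row.names = FALSE)
  p <- model$params
  wm(p$Wc, "conv_weights.csv"); wm(p$centers, "fuzzy_centers.csv")
  wm(p$Mf, "fuzzy_mixing.csv")
  scal <- list(bc = p$bc, mix = p$mix, widths = p$widths,
               wd = p$wd, wf = p$wf, b = p$b)
  meta <- list(config = unclass(model$config), seed = model$seed,
               scalars = scal, classes = model$classes)
  if (!is.null(model$fc)) {
    wm(model$fc$W, "fc_weights.csv")
    meta$fcBias <- model$fc$b
    meta$scalerCenter <- model$scaler$center
    meta$scalerScale <- model$scaler$scale
  }
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$eigenModel))
    saveEigenModel(model$eigenModel, file.path(dir, "eigen_model"))
  invisible(dir)
}

#' Load an FDCNet model saved by [saveFDCNetModel()]
#'
#' Validates the stored array shapes against the configuration.
#'
#' @param dir archive directory.
#' @return An \code{FDCNetModel}.
#' @export
loadFDCNetModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(fdcnetConfig, meta$config[setdiff(names(meta$config),
                                                   character(0))])
  rm_ <- function(f) as.matrix(utils::read.csv(file.path(dir, f)))
  params <- list(Wc = unname(rm_("conv_weights.csv")),
                 bc = meta$scalars$bc, mix = meta$scalars$mix,
                 centers = unname(rm_("fuzzy_centers.csv")),
                 widths = meta$scalars$widths,
                 Mf = unname(rm_("fuzzy_mixing.csv")),
                 wd = meta$scalars$wd, wf = meta$scalars$wf,
                 b = meta$scalars$b)
  K <- as.integer(cfg$filterSize^length(cfg$inputShape))
  if (!identical(dim(params$Wc), c(K, cfg$convChannels)))
    stop("loadFDCNetModel: conv weight shape does not match the config")
  if (!identical(dim(params$centers),
                 c(cfg$fuzzyUnits, cfg$convChannels)))
    stop("loadFDCNetModel: fuzzy center shape does not match the config")
  model <- structure(list(config = cfg, params = params,
                          seed = as.integer(meta$seed %||% NA_integer_),
                          fc = NULL, scaler = NULL, eigenModel = NULL,
                          classes = meta$classes),
                     class = "FDCNetModel")
  if (file.exists(file.path(dir, "fc_weights.csv"))) {
    model$fc <- list(W = unname(rm_("fc_weights.csv")), b = meta$fcBias)
    model$scaler <- list(center = meta$scalerCenter,
                         scale = meta$scalerScale)
  }
  if (file.exists(file.path(dir, "eigen_model", "model.json")))
    model$eigenModel <- loadEigenModel(file.path(dir, "eigen_model"))
  model
}
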