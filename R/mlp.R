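# Minimal multilayer perceptron in base R matrix code: linear layers with
# batch normalisation, ReLU and dropout on the hidden layers, a bias-free
# final linear layer (Bradley-Terry scores are translation-invariant, so a
# final bias is unidentifiable), Adam with decoupled-from-nothing classic
# L2 weight decay added to the gradient. Gradients are verified against
# finite differences in the test suite.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# He-initialised parameters. Hidden layers carry (W, b, gamma, beta) plus
# batch-norm running statistics; the output layer carries W only.
mlpInit <- function(inputDim, hiddenDims, seed) {
  dims <- c(inputDim, hiddenDims, 1L)
  withSeed(seed, {
    layers <- vector("list", length(dims) - 1L)
    for (j in seq_along(layers)) {
      fanIn <- dims[j]
      W <- matrix(stats::rnorm(fanIn * dims[j + 1L], sd = sqrt(2 / fanIn)),
                  nrow = fanIn)
      if (j < length(layers)) {
        layers[[j]] <- list(W = W, b = numeric(dims[j + 1L]),
                            gamma = rep(1, dims[j + 1L]),
                            beta = numeric(dims[j + 1L]),
                            runMean = numeric(dims[j + 1L]),
                            runVar = rep(1, dims[j + 1L]))
      } else {
        layers[[j]] <- list(W = W)
      }
    }
    layers
  })
}

# Forward pass. training = TRUE uses batch statistics (and updates the
# running averages in the returned layers) and samples dropout masks from
# the current RNG stream; training = FALSE uses running statistics with
# dropout disabled. Returns scores plus the caches backward needs.
mlpForward <- function(layers, X, dropout, training = FALSE) {
  nHidden <- length(layers) - 1L
  caches <- vector("list", nHidden)
  A <- X
  for (j in seq_len(nHidden)) {
    ly <- layers[[j]]
    Z <- sweep(A %*% ly$W, 2L, ly$b, "+")
    if (training) {
      m <- nrow(Z)
      mu <- colMeans(Z)
      ctr <- sweep(Z, 2L, mu)
      v <- colMeans(ctr^2)
      invStd <- 1 / sqrt(v + .BN_EPS)
      Zhat <- sweep(ctr, 2L, invStd, "*")
      unb <- if (m > 1L) v * m / (m - 1L) else v
      layers[[j]]$runMean <- (1 - .BN_MOMENTUM) * ly$runMean + .BN_MOMENTUM * mu
      layers[[j]]$runVar <- (1 - .BN_MOMENTUM) * ly$runVar + .BN_MOMENTUM * unb
    } else {
      invStd <- 1 / sqrt(ly$runVar + .BN_EPS)
      Zhat <- sweep(sweep(Z, 2L, ly$runMean), 2L, invStd, "*")
      ctr <- NULL
    }
    B <- sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    relu <- B > 0
    A2 <- B * relu
    if (training && dropout > 0) {
      mask <- (matrix(stats::runif(length(A2)), nrow(A2)) >= dropout) /
        (1 - dropout)
      A2 <- A2 * mask
    } else mask <- NULL
    caches[[j]] <- list(input = A, ctr = ctr, invStd = invStd, Zhat = Zhat,
                        relu = relu, mask = mask)
    A <- A2
  }
  list(scores = as.numeric(A %*% layers[[length(layers)]]$W),
       final_input = A, caches = caches, layers = layers)
}

# Backward pass for a training-mode forward. dScores: dLoss/dscore per row.
# Returns gradients in the same shape as the layers list.
mlpBackward <- function(layers, fwd, dScores) {
  nL <- length(layers)
  grads <- vector("list", nL)
  dS <- matrix(dScores, ncol = 1L)
  grads[[nL]] <- list(W = crossprod(fwd$final_input, dS))
  dA <- dS %*% t(layers[[nL]]$W)
  for (j in rev(seq_len(nL - 1L))) {
    ca <- fwd$caches[[j]]
    ly <- layers[[j]]
    if (!is.null(ca$mask)) dA <- dA * ca$mask
    dB <- dA * ca$relu
    dgamma <- colSums(dB * ca$Zhat)
    dbeta <- colSums(dB)
    dZhat <- sweep(dB, 2L, ly$gamma, "*")
    m <- nrow(dZhat)
    # batch-norm backward (batch statistics)
    s1 <- colSums(dZhat)
    s2 <- colSums(dZhat * ca$Zhat)
    dZ <- sweep(dZhat, 2L, s1 / m) - sweep(ca$Zhat, 2L, s2 / m, "*")
    dZ <- sweep(dZ, 2L, ca$invStd, "*")
    grads[[j]] <- list(W = crossprod(ca$input, dZ), b = colSums(dZ),
                       gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

adamInit <- function(layers) {
  lapply(layers, function(ly) {
    p <- ly[intersect(names(ly), c("W", "b", "gamma", "beta"))]
    list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
         t = 0L)
  })
}

# One Adam update in place; weight decay applies to weight matrices only.
adamStep <- function(layers, grads, state, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (j in seq_along(layers)) {
    st <- state[[j]]
    st$t <- st$t + 1L
    for (nm in names(st$m)) {
      g <- grads[[j]][[nm]]
      if (nm == "W") g <- g + weightDecay * layers[[j]][[nm]]
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
      mhat <- st$m[[nm]] / (1 - beta1^st$t)
      vhat <- st$v[[nm]] / (1 - beta2^st$t)
      layers[[j]][[nm]] <- layers[[j]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state[[j]] <- st
  }
  list(layers = layers, state = state)
}

# Scores in evaluation mode (running batch-norm statistics, no dropout).
mlpPredict <- function(layers, X) {
  mlpForward(layers, X, dropout = 0, training = FALSE)$scores
}
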