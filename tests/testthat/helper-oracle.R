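# Independent, deliberately naive reference implementation of the
# entropy-weight + TOPSIS pipeline, written with explicit loops straight
# from the textbook definitions. It exists only to cross-check the package
# and shares no code with it.

oracle_entropy_topsis <- function(x, orientation = rep("benefit", ncol(x))) {
  n <- nrow(x)
  p <- ncol(x)
  ent <- numeric(p)
  for (j in seq_len(p)) {
    pr <- x[, j] / sum(x[, j])
    acc <- 0
    for (i in seq_len(n)) if (pr[i] > 0) acc <- acc + pr[i] * log(pr[i])
    ent[j] <- -acc / log(n)
  }
  util <- 1 - ent
  w <- util / sum(util)

  v <- matrix(0, n, p)
  for (j in seq_len(p)) {
    nrm <- sqrt(sum(x[, j]^2))
    for (i in seq_len(n)) v[i, j] <- w[j] * x[i, j] / nrm
  }
  best <- numeric(p)
  worst <- numeric(p)
  for (j in seq_len(p)) {
    if (orientation[j] == "benefit") {
      best[j] <- max(v[, j]); worst[j] <- min(v[, j])
    } else {
      best[j] <- min(v[, j]); worst[j] <- max(v[, j])
    }
  }
  dplus <- numeric(n)
  dminus <- numeric(n)
  for (i in seq_len(n)) {
    dplus[i] <- sqrt(sum((v[i, ] - best)^2))
    dminus[i] <- sqrt(sum((v[i, ] - worst)^2))
  }
  list(entropy = ent, utility = util, weight = w,
       dplus = dplus, dminus = dminus, ci = dminus / (dplus + dminus))
}

# random strictly positive decision matrix with labels
random_matrix <- function(n, p) {
  matrix(runif(n * p, 0.5, 100), n, p,
         dimnames = list(sprintf("s%d", seq_len(n)),
                         sprintf("ind%d", seq_len(p))))
}

# Two-block panel with genuinely two-dimensional structure: four indicators
# follow one latent trait and two another, strain s1 leads on both traits
# (and leans toward the majority block), so s1 and the majority of the
# benefit loadings provably share a PC1/PC2 quadrant with clear margins and
# an untied 4:2 loading count. Used for the biplot co-location checks.
two_factor_panel <- function() {
  u <- c(5.0, 3.5, 3.0, 2.2, 1.5, 0.8)   # block-A latent trait
  w <- c(4.0, 3.8, 1.0, 3.5, 0.5, 2.0)   # block-B latent trait
  e <- matrix(c( 0.05, -0.03,  0.04, -0.02,
                -0.04,  0.02, -0.01,  0.03,
                 0.02, -0.05,  0.03,  0.01,
                -0.01,  0.04, -0.03, -0.02,
                 0.03,  0.01, -0.04,  0.05,
                -0.05, -0.01,  0.02, -0.04), 6, 4, byrow = TRUE)
  x <- cbind(outer(u, c(1.0, 0.9, 1.1, 0.95)) + e,
             outer(w, c(1.0, 1.05))) + 10
  dimnames(x) <- list(sprintf("s%d", 1:6), sprintf("ind%d", 1:6))
  x
}
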