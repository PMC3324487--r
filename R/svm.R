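## Linear soft-margin SVM trained by dual coordinate descent.
##
## Solves min_w 1/2 ||w||^2 + C sum_k max(0, 1 - y_k w.x_k) in the dual:
##   min_a 1/2 a' Q a - e' a,  0 <= a_k <= C,  Q_kl = y_k y_l x_k.x_l
## with the bias handled by an augmented constant feature (regularized
## bias, the standard linear-solver formulation). Updates sweep the
## samples in a fixed order, so training is deterministic. Suitable for
## the small panel-classifier problems here (tens of samples, up to a
## few hundred markers).

svm_dcd <- function(X, y, cost = 1, max_iter = 10000, tol = 1e-8) {
  ## X: samples x features (already scaled); y in {-1, +1}
  n <- nrow(X)
  Xa <- cbind(X, 1)  # augmented bias feature
  qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  for (iter in seq_len(max_iter)) {
    max_delta <- 0
    for (k in seq_len(n)) {
      g <- y[k] * sum(w * Xa[k, ]) - 1
      pg <- g
      if (alpha[k] <= 0) pg <- min(g, 0)
      if (alpha[k] >= cost) pg <- max(g, 0)
      if (abs(pg) > 1e-14) {
        a_old <- alpha[k]
        alpha[k] <- min(max(alpha[k] - g / qii[k], 0), cost)
        d <- alpha[k] - a_old
        if (d != 0) {
          w <- w + d * y[k] * Xa[k, ]
          max_delta <- max(max_delta, abs(d))
        }
      }
    }
    if (max_delta < tol) {
      return(list(w = w[-length(w)], b = w[length(w)], alpha = alpha,
                  iterations = iter, converged = TRUE))
    }
  }
  stop("SVM training did not converge after ", max_iter,
       " sweeps (max alpha change ", format(max_delta), "); ",
       "check for degenerate or unscaled inputs")
}
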