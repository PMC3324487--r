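## Independent brute-force oracles. These deliberately avoid the package's
## own code paths: enumeration, all-pairs counting and transitive closure.

## Exact two-sided rank-sum p-value by enumeration of all C(n, n1) rank
## assignments (tie-free data only).
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- utils::combn(n, n1, FUN = sum) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Step-up FDR adjustment computed literally from its definition:
## adj_(i) = min_{j >= i} p_(j) * n / j on the sorted scale.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o] * n / seq_len(n)
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(sorted[i:n]))
  out <- numeric(n)
  out[o] <- adj
  out
}

## AUC as the literal all-pairs probability.
oracle_auc <- function(case, control) {
  s <- 0
  for (a in case) for (b in control) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(case) * length(control))
}

## Exact two-sided Spearman p by full permutation enumeration (n! perms).
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  ry <- rank(y)
  pm <- perms(seq_along(y))
  rhos <- apply(pm, 1, function(idx) stats::cor(rank(x), ry[idx],
                                                method = "pearson"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

## Transitive-closure partition oracle for matching: features i, j are
## "identical" if their mass and time deviations both fall inside the
## windows evaluated at the pair midpoint; clusters are the connected
## components. Returns NULL when the components are not window-consistent
## (some component is not a clique, or holds two features of one sample),
## in which case the greedy algorithm is not required to agree.
oracle_match_partition <- function(feats, scheme = tolerance_scheme()) {
  n <- nrow(feats)
  m <- feats$mass_da
  t <- feats$time_min
  mbar <- outer(m, m, "+") / 2
  tbar <- outer(t, t, "+") / 2
  dm <- abs(outer(m, m, "-")) / (mbar * mass_tolerance(mbar, scheme) * 1e-6)
  dt <- abs(outer(t, t, "-")) / time_tolerance(tbar, scheme)
  adj <- pmax(dm, dt) <= 1
  ## connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  comp <- match(comp, unique(comp))
  ## window consistency: every component must be a clique with at most
  ## one feature per sample
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) > 1) {
      if (!all(adj[idx, idx])) return(NULL)
      if (anyDuplicated(feats$sample_id[idx])) return(NULL)
    }
  }
  comp
}

## Canonical form of a partition for comparison.
partition_key <- function(comp) {
  unname(split(seq_along(comp), comp))[order(vapply(
    unname(split(seq_along(comp), comp)), min, numeric(1)))]
}
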