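# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route (brute force, quadrature, matrix
# exponential, exhaustive search) and never calls the code path under test.

# AUC by explicit pair counting over all (positive, negative) pairs.
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Stratified paired bootstrap of the AUC difference between two score
# vectors on the same subjects: cases and controls resampled separately,
# each subject keeping both scores.
delong_bootstrap_oracle <- function(scores_a, scores_b, truth, n_boot,
                                    seed) {
  set.seed(seed)
  idx_pos <- which(truth)
  idx_neg <- which(!truth)
  fast_auc <- function(s, pos_idx, neg_idx) {
    pos <- s[pos_idx]
    neg <- s[neg_idx]
    psi <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(psi)
  }
  deltas <- vapply(seq_len(n_boot), function(b) {
    rp <- sample(idx_pos, replace = TRUE)
    rn <- sample(idx_neg, replace = TRUE)
    fast_auc(scores_a, rp, rn) - fast_auc(scores_b, rp, rn)
  }, numeric(1))
  stats::var(deltas)
}

# Two-compartment tissue impulse response by matrix exponential of the ODE
# system dC1/dt = -(k2+k3) C1 + k4 C2 (+ K1 delta input), dC2/dt = k3 C1 -
# k4 C2; the vascular plateau delays the compartment response by Tc.
ode_impulse_oracle <- function(params, t) {
  A <- matrix(c(-(params$k2 + params$k3), params$k4,
                params$k3, -params$k4), 2, 2, byrow = TRUE)
  vapply(t, function(ti) {
    if (ti < params$Tc) return(params$K1)
    tau_min <- (ti - params$Tc) / 60
    state <- as.numeric(Matrix::expm(A * tau_min) %*% c(params$K1, 0))
    sum(state)
  }, numeric(1))
}

# Frame-averaged tissue activity by nested adaptive quadrature:
# outer integral over the frame, inner convolution integral split at the
# kinks of the impulse response.
quadrature_tac_oracle <- function(params, aif, schedule) {
  ca <- function(u) {
    vapply(u, function(ui) {
      if (ui < params$delay) 0 else evaluate_aif(aif, ui - params$delay)
    }, numeric(1))
  }
  conv_at <- function(ti) {
    if (ti <= 0) return(0)
    integrand <- function(u) {
      ca(u) * impulse_response(params, ti - u) / 60  # per-second kernel
    }
    cuts <- sort(unique(pmin(pmax(c(0, ti - params$Tc, ti), 0), ti)))
    total <- 0
    for (k in seq_len(length(cuts) - 1L)) {
      if (cuts[k + 1L] - cuts[k] < 1e-12) next
      total <- total + stats::integrate(integrand, cuts[k], cuts[k + 1L],
                                        rel.tol = 1e-9,
                                        subdivisions = 400L)$value
    }
    total
  }
  tissue_at <- function(ti) {
    (1 - params$vb) * conv_at(ti) + params$vb * ca(ti)
  }
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$frame_start[i]
    b <- a + schedule$frame_duration[i]
    stats::integrate(Vectorize(tissue_at), a, b, rel.tol = 1e-7,
                     subdivisions = 400L)$value / (b - a)
  }, numeric(1))
}

# Independent recursive exhaustive CART: plain loops, Gini from scratch.
# Returns a nested list mirroring the grown tree's split structure.
tree_oracle <- function(features, labels, min_split) {
  gini <- function(y) {
    p <- mean(y)
    2 * p * (1 - p)
  }
  grow <- function(X, y) {
    node <- list(n = length(y), event_rate = mean(y))
    if (length(y) < min_split || gini(y) == 0) return(node)
    best <- NULL
    for (j in seq_along(X)) {
      v <- sort(unique(X[[j]]))
      if (length(v) < 2) next
      for (k in seq_len(length(v) - 1)) {
        thr <- (v[k] + v[k + 1]) / 2
        left <- X[[j]] < thr
        gain <- length(y) * gini(y) -
          (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left]))
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(j = j, thr = thr, gain = gain)
        }
      }
    }
    if (is.null(best)) return(node)
    left <- X[[best$j]] < best$thr
    node$feature <- names(X)[best$j]
    node$threshold <- best$thr
    node$left <- grow(lapply(X, `[`, left), y[left])
    node$right <- grow(lapply(X, `[`, !left), y[!left])
    node
  }
  grow(as.list(features), as.logical(labels))
}

# Flatten a grown rpa_tree into the oracle's nested shape for comparison.
tree_to_oracle_shape <- function(tree) {
  walk <- function(node) {
    out <- list(n = node$n, event_rate = node$event_rate)
    if (!is.null(node$split)) {
      out$feature <- node$split$feature
      out$threshold <- node$split$threshold
      out$left <- walk(node$left)
      out$right <- walk(node$right)
    }
    out
  }
  walk(tree$root)
}

# Exhaustive minimum of R(T) + penalty * #leaves over all pruned subtrees.
prune_oracle_cost <- function(shape, penalty, n_gini) {
  # shape: oracle-shaped tree; n_gini(node) gives count-weighted impurity
  walk <- function(node) {
    leaf_cost <- n_gini(node) + penalty
    if (is.null(node$feature)) return(leaf_cost)
    min(leaf_cost, walk(node$left) + walk(node$right))
  }
  walk(shape)
}
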