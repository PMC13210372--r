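# Training objectives: evidential regression loss with annealed KL
# regularizer, ordinal squared-CDF loss, concept binary cross-entropy, graph
# sparsity, and the NT-Xent contrastive loss. Each supervised loss returns
# both its value and its analytic gradient (verified against finite
# differences in the test suite).

onehot4 <- function(y) { v <- numeric(4); v[y + 1] <- 1; v }

#' Evidential loss for one sample
#'
#' Brier-type evidential regression on the Dirichlet mean plus a variance
#' term, with a KL-to-uniform regularizer on the misleading evidence
#' (true-class evidence pinned at 1), annealed via `lambda`.
#'
#' @param alpha Dirichlet parameters (length 4, each >= 1)
#' @param y true class in 0..3
#' @param lambda KL regularizer weight (annealed toward 1 during training)
#' @return list: `value`, `grad` (dL/dalpha)
#' @export
loss_evidential <- function(alpha, y, lambda = 1) {
  S <- sum(alpha)
  p <- alpha / S
  yk <- onehot4(y)
  v1 <- sum((yk - p)^2)
  v2 <- sum(p * (1 - p)) / (S + 1)
  # gradients through p and S
  dp1 <- 2 * (p - yk)
  dp2 <- (1 - 2 * p) / (S + 1)
  dS2 <- -sum(p * (1 - p)) / (S + 1)^2
  dalpha <- numeric(4)
  for (j in 1:4) {
    dp_da <- (as.numeric(seq_len(4) == j) - p) / S
    dalpha[j] <- sum((dp1 + dp2) * dp_da) + dS2
  }
  value <- v1 + v2
  if (lambda > 0) {
    at <- yk + (1 - yk) * alpha       # misleading evidence only
    St <- sum(at)
    kl <- lgamma(St) - sum(lgamma(at)) - lgamma(4) +
      sum((at - 1) * (digamma(at) - digamma(St)))
    dkl_dat <- (at - 1) * trigamma(at) - trigamma(St) * sum(at - 1)
    value <- value + lambda * kl
    dalpha <- dalpha + lambda * dkl_dat * (1 - yk)
  }
  list(value = value, grad = dalpha)
}

#' Ordinal squared-CDF loss for one sample
#'
#' Squared difference between the predicted and true cumulative label
#' distributions over the ordered levels 0..3 (an earth-mover-style penalty
#' that charges distant misclassifications more).
#'
#' @param alpha Dirichlet parameters
#' @param y true class in 0..3
#' @return list: `value`, `grad` (dL/dalpha)
#' @export
loss_ordinal <- function(alpha, y) {
  S <- sum(alpha)
  p <- alpha / S
  P <- cumsum(p)
  Y <- as.numeric(seq(0, 3) >= y)
  diffs <- P - Y
  value <- sum(diffs^2)
  dP <- 2 * diffs
  dp <- rev(cumsum(rev(dP)))          # dL/dp_k = sum_{m >= k} dP_m
  dalpha <- (dp - sum(dp * p)) / S
  list(value = value, grad = dalpha)
}

#' Graph sparsity penalty
#'
#' Mean L1 norm of the off-diagonal entries of the gated masked adjacency.
#' Entries are non-negative, so the penalty is their mean.
#'
#' @param Aeff gated masked adjacency (`At * M`)
#' @return list: `value`, `grad` (dL/dAeff)
#' @export
loss_sparsity <- function(Aeff) {
  n <- nrow(Aeff)
  denom <- n * (n - 1)
  off <- Aeff
  diag(off) <- 0
  g <- matrix(sign(off) / denom, n, n)
  diag(g) <- 0
  list(value = sum(abs(off)) / denom, grad = g)
}

#' Concept supervision loss (binary cross-entropy on the 3 x 12 heads)
#'
#' @param concept_matrix 3 x 12 matrix of head activations in (0, 1)
#' @param labels 12 binary concept labels (NA = unlabeled, contributes 0)
#' @return mean BCE over labeled entries (all three modality rows are
#'   supervised toward the same label)
#' @export
loss_concept <- function(concept_matrix, labels) {
  ok <- !is.na(labels)
  if (!any(ok)) return(0)
  P <- clamp(concept_matrix[, ok, drop = FALSE], 1e-12, 1 - 1e-12)
  L <- matrix(labels[ok], 3, sum(ok), byrow = TRUE)
  -mean(L * log(P) + (1 - L) * log(1 - P))
}

#' NT-Xent contrastive loss
#'
#' For 2N projections from N samples' two augmented views:
#' `-log exp(sim(z_i, z_j)/t) / sum_{k != i} exp(sim(z_i, z_k)/t)`,
#' averaged over all 2N anchors; `sim` is cosine similarity.
#'
#' @param Z 2N x d matrix of projections (rows)
#' @param pair_index integer vector of length 2N; `pair_index[i]` is the row
#'   of `i`'s positive partner
#' @param temperature softmax temperature (> 0), default 0.1
#' @return scalar loss
#' @export
contrastive_loss <- function(Z, pair_index, temperature = 0.1) {
  n2 <- nrow(Z)
  if (n2 < 4) np_stop("np_insufficient_batch_error",
                      "need at least N = 2 samples (4 views), got %d rows", n2)
  if (temperature <= 0) np_stop("np_validation_error", "temperature must be > 0")
  Zn <- Z / sqrt(rowSums(Z^2))
  sim <- Zn %*% t(Zn) / temperature
  total <- 0
  for (i in seq_len(n2)) {
    logits <- sim[i, -i]
    denom <- log(sum(exp(logits - max(logits)))) + max(logits)
    total <- total + (denom - sim[i, pair_index[i]])
  }
  total / n2
}

#' Combine the six component losses with the multi-task weights
#'
#' @param components named list/vector with `concept`, `ordinal`,
#'   `evidential`, `sparsity`, `meta`, `contrast`
#' @param weights a [loss_weights()]
#' @return weighted-sum scalar
#' @export
total_loss <- function(components, weights = loss_weights()) {
  comp <- unlist(components)
  need <- c("concept", "ordinal", "evidential", "sparsity", "meta", "contrast")
  if (!all(need %in% names(comp)))
    np_stop("np_validation_error", "components must name all six losses")
  if (any(!is.finite(comp[need])))
    np_stop("np_validation_error", "loss components must be finite")
  sum(unlist(weights)[c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")] *
        comp[need])
}

#' Multi-task loss weights
#'
#' Defaults: alpha = 1.0 (concept supervision), beta = 2.0 (ordinal ranking),
#' gamma = 0.5 (evidential), delta = 0.1 (graph sparsity), epsilon = 0.8
#' (meta), zeta = 0.3 (contrastive).
#'
#' @param alpha,beta,gamma,delta,epsilon,zeta non-negative weights
#' @return named list of weights
#' @export
loss_weights <- function(alpha = 1.0, beta = 2.0, gamma = 0.5, delta = 0.1,
                         epsilon = 0.8, zeta = 0.3) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            epsilon = epsilon, zeta = zeta)
  if (any(unlist(w) < 0))
    np_stop("np_validation_error", "loss weights must be non-negative")
  w
}
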