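# Concept-graph fusion network.
#
# The 12 concepts are graph nodes with activation-scaled embedding features.
# A pairwise MLP builds the adjacency (row softmax over j != i), missing
# modalities zero out incident edges (with row renormalization over the
# surviving columns), sigmoid edge gates modulate propagation, two GraphSAGE
# layers propagate, mean pooling over unmasked nodes feeds an evidential
# Dirichlet head. Forward passes are plain matrix code; the backward pass for
# the trainable subset (GraphSAGE weights, gates, evidential head, per-infant
# adjacency offset) is hand-derived and verified against finite differences.

HID <- 128L
N_CONCEPTS <- 12L
N_CLASSES <- 4L

he_init <- function(nr, nc, fan_in = nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Initialize fusion-model parameters
#'
#' @param seed RNG seed for reproducible initialization
#' @param d hidden dimension (128)
#' @return named list of parameter arrays (class `np_params`)
#' @export
init_fusion_params <- function(seed = 42L, d = HID) {
  with_seed(seed, {
    p <- list(
      emb_E = matrix(stats::rnorm(12 * d, 0, 1), 12, d),
      emb_B = matrix(stats::rnorm(12 * d, 0, 0.1), 12, d),
      adj_W1 = he_init(64, 3 * d), adj_b1 = numeric(64),
      adj_w2 = stats::rnorm(64, 0, sqrt(1 / 64)), adj_b2 = 0,
      gates_G = matrix(2, 12, 12),            # sigmoid(2) ~ 0.88: open gates
      sage_W1s = he_init(d, d), sage_W1n = he_init(d, d), sage_b1 = numeric(d),
      sage_W2s = he_init(d, d), sage_W2n = he_init(d, d), sage_b2 = numeric(d),
      ev_W = matrix(stats::rnorm(4 * d, 0, 0.1 / sqrt(d)), 4, d),
      ev_b = rep(0.01, 4),
      delta_A = matrix(0, 12, 12),
      head_W_v = he_init(12, d), head_b_v = numeric(12),
      head_W_a = he_init(12, d), head_b_a = numeric(12),
      head_W_p = he_init(12, d), head_b_p = numeric(12)
    )
    structure(p, class = "np_params")
  })
}

# Parameters adapted per infant; everything else stays frozen under
# personalization (concept-consistency contract).
ADAPTABLE <- c("ev_W", "ev_b", "delta_A")

#' Build the concept adjacency matrix
#'
#' Pairwise scores from a 2-layer perceptron (hidden 64) on
#' `[h_i; h_j; |h_i - h_j|]`, followed by a row-wise softmax over `j != i`.
#' Self-edges are excluded (zero diagonal).
#'
#' @param H 12 x 128 node feature matrix
#' @param params parameter list (uses `adj_*`)
#' @return 12 x 12 row-stochastic adjacency with zero diagonal
#' @export
build_adjacency <- function(H, params = init_fusion_params()) {
  n <- nrow(H)
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), n)
  off <- ii != jj
  X <- cbind(H[ii[off], , drop = FALSE], H[jj[off], , drop = FALSE],
             abs(H[ii[off], , drop = FALSE] - H[jj[off], , drop = FALSE]))
  Z <- pmax(X %*% t(params$adj_W1) +
              matrix(params$adj_b1, nrow(X), 64, byrow = TRUE), 0)
  s <- as.numeric(Z %*% params$adj_w2 + params$adj_b2)
  S <- matrix(-Inf, n, n)
  S[cbind(ii[off], jj[off])] <- s
  A <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r[is.finite(r)]))
    e[!is.finite(r)] <- 0
    e / sum(e)
  }))
  A
}

node_mask_from_modalities <- function(modality_mask) {
  stopifnot(length(modality_mask) == 3)
  rep(as.logical(modality_mask), each = 4L)
}

#' Mask the adjacency for missing modalities
#'
#' Zeroes every edge incident to a masked concept node and renormalizes the
#' surviving rows over the surviving columns. Rows that lose all mass stay
#' zero.
#'
#' @param A row-stochastic adjacency from [build_adjacency()]
#' @param mask either 3 modality booleans (video, audio, physio) or 12
#'   per-node booleans; `TRUE` = present
#' @return masked, renormalized adjacency
#' @export
mask_adjacency <- function(A, mask) {
  m <- if (length(mask) == 3) node_mask_from_modalities(mask) else as.logical(mask)
  if (!any(m)) np_stop("np_empty_graph_error", "all concept nodes are masked")
  if (all(m)) return(A)
  At <- A
  At[!m, ] <- 0
  At[, !m] <- 0
  rs <- rowSums(At)
  nz <- which(m & rs > 0)
  At[nz, ] <- At[nz, , drop = FALSE] / rs[nz]
  At
}

#' GraphSAGE propagation and pooling
#'
#' Two layers of `ReLU(W_self h_i + W_nbr sum_j (A*M)_ij h_j + b)` followed by
#' a mean pool over unmasked nodes.
#'
#' @param H 12 x 128 node features
#' @param At masked adjacency
#' @param M 12 x 12 edge gate matrix in \[0,1\] (sigmoid of `gates_G`)
#' @param params parameter list (uses `sage_*`)
#' @param node_mask 12 booleans; `TRUE` = pooled
#' @return list: `h_gnn` (128), plus cached intermediates for backprop
#' @export
propagate_and_pool <- function(H, At, M, params, node_mask = rep(TRUE, 12)) {
  if (!any(node_mask)) np_stop("np_empty_graph_error", "no unmasked nodes to pool")
  Aeff <- At * M
  b1 <- matrix(params$sage_b1, 12, HID, byrow = TRUE)
  b2 <- matrix(params$sage_b2, 12, HID, byrow = TRUE)
  Z1 <- H %*% params$sage_W1s + (Aeff %*% H) %*% params$sage_W1n + b1
  H1 <- pmax(Z1, 0)
  H1[!node_mask, ] <- 0
  Z2 <- H1 %*% params$sage_W2s + (Aeff %*% H1) %*% params$sage_W2n + b2
  H2 <- pmax(Z2, 0)
  H2[!node_mask, ] <- 0
  h_gnn <- colMeans(H2[node_mask, , drop = FALSE])
  list(h_gnn = h_gnn, Aeff = Aeff, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2)
}

#' Evidential Dirichlet output head
#'
#' `alpha = ReLU(W h + b) + 1`; epistemic uncertainty `u = K / sum(alpha)`;
#' class probabilities `p = alpha / sum(alpha)`.
#'
#' @param h_gnn 128-dim fused representation
#' @param params parameter list (uses `ev_W`, `ev_b`)
#' @return object of class `np_evidential`: `alpha`, `u`, `p`, `evidence`
#' @export
evidential_forward <- function(h_gnn, params) {
  e <- as.numeric(params$ev_W %*% h_gnn + params$ev_b)
  ev <- pmax(e, 0)
  alpha <- ev + 1
  S <- sum(alpha)
  structure(list(alpha = alpha, evidence = ev, u = N_CLASSES / S,
                 p = alpha / S, logits = e),
            class = "np_evidential")
}

#' Predict a pain level or abstain
#'
#' Abstains iff `u > tau`; otherwise argmax of `p`, with exact probability
#' ties broken toward the higher severity class (and flagged).
#'
#' @param ev an `np_evidential` from [evidential_forward()]
#' @param tau abstention threshold in (0, 1\]; default 0.5
#' @return list: `abstain`, `level` (NA when abstaining), `tie`, `u`
#' @export
predict_or_abstain <- function(ev, tau = 0.5) {
  stopifnot(tau > 0, tau <= 1)
  if (ev$u > tau) {
    return(list(abstain = TRUE, level = NA_integer_, tie = FALSE, u = ev$u))
  }
  best <- max(ev$p)
  winners <- which(ev$p >= best - 1e-12)
  list(abstain = FALSE, level = max(winners) - 1L,
       tie = length(winners) > 1, u = ev$u)
}

#' Full fusion forward pass from a concept vector
#'
#' @param cv an `np_concept_vector`
#' @param params parameter list
#' @param modality_mask optional 3 booleans (video, audio, physio); combined
#'   with the concept availability to form the node mask
#' @return list with `ev` (evidential output), `h_gnn`, node mask, and cached
#'   intermediates
#' @export
fusion_forward <- function(cv, params, modality_mask = NULL) {
  mask <- unname(cv$available)
  if (!is.null(modality_mask)) {
    mask <- mask & node_mask_from_modalities(modality_mask)
  }
  if (!any(mask)) np_stop("np_empty_graph_error", "no available concept nodes")
  act <- unname(cv$activations)
  act[!mask] <- 0
  H <- act * params$emb_E + params$emb_B
  A <- build_adjacency(H, params)
  Araw <- pmax(A + params$delta_A, 0)
  diag(Araw) <- 0
  B <- Araw
  B[!mask, ] <- 0
  B[, !mask] <- 0
  rs <- rowSums(B)
  At <- B
  nz <- which(mask & rs > 0)
  At[nz, ] <- At[nz, , drop = FALSE] / rs[nz]
  M <- stats::plogis(params$gates_G)
  diag(M) <- 0
  pp <- propagate_and_pool(H, At, M, params, node_mask = mask)
  ev <- evidential_forward(pp$h_gnn, params)
  c(list(ev = ev, mask = mask, H = H, A = A, Araw = Araw, B = B, rs = rs,
         At = At, M = M, act = act), pp)
}

# Backward pass: gradient of a scalar loss wrt the trainable subset, given
# dL/dalpha at the evidential head. Returns a named list of gradients.
fusion_backward <- function(fw, params, dalpha, dAeff_extra = NULL) {
  mask <- fw$mask
  n_un <- sum(mask)
  # Leaky subgradient through the evidence ReLU so that classes whose
  # evidence has collapsed to zero can recover during training.
  de <- dalpha * ifelse(fw$ev$logits > 0, 1, 0.1)
  g_ev_W <- outer(de, fw$h_gnn)
  g_ev_b <- de
  dh <- as.numeric(t(params$ev_W) %*% de)

  dH2 <- matrix(0, 12, HID)
  dH2[mask, ] <- matrix(dh / n_un, n_un, HID, byrow = TRUE)
  dZ2 <- dH2 * (fw$Z2 > 0)
  dZ2[!mask, ] <- 0
  N1 <- fw$Aeff %*% fw$H1
  g_W2s <- t(fw$H1) %*% dZ2
  g_W2n <- t(N1) %*% dZ2
  g_b2 <- colSums(dZ2)
  P1 <- fw$H1 %*% params$sage_W2n
  dAeff <- dZ2 %*% t(P1)
  dH1 <- dZ2 %*% t(params$sage_W2s) + t(fw$Aeff) %*% (dZ2 %*% t(params$sage_W2n))

  dZ1 <- dH1 * (fw$Z1 > 0)
  dZ1[!mask, ] <- 0
  N0 <- fw$Aeff %*% fw$H
  g_W1s <- t(fw$H) %*% dZ1
  g_W1n <- t(N0) %*% dZ1
  g_b1 <- colSums(dZ1)
  P0 <- fw$H %*% params$sage_W1n
  dAeff <- dAeff + dZ1 %*% t(P0)
  if (!is.null(dAeff_extra)) dAeff <- dAeff + dAeff_extra

  dM <- dAeff * fw$At
  g_G <- dM * fw$M * (1 - stats::plogis(params$gates_G))
  diag(g_G) <- 0

  dAt <- dAeff * fw$M
  # back through row renormalization At = B / rs
  dB <- matrix(0, 12, 12)
  nz <- which(mask & fw$rs > 0)
  for (i in nz) {
    di <- dAt[i, ]
    dB[i, ] <- (di - sum(di * fw$At[i, ])) / fw$rs[i]
  }
  dB[, !mask] <- 0
  g_delta <- dB * (fw$Araw > 0)
  diag(g_delta) <- 0

  list(ev_W = g_ev_W, ev_b = g_ev_b,
       sage_W1s = g_W1s, sage_W1n = g_W1n, sage_b1 = g_b1,
       sage_W2s = g_W2s, sage_W2n = g_W2n, sage_b2 = g_b2,
       gates_G = g_G, delta_A = g_delta)
}
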