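# Concept-graph construction, masking, propagation, evidential head.

random_cv <- function(seed = 1, avail = rep(TRUE, 12)) {
  set.seed(seed)
  concept_vector(stats::runif(12), avail, rep(FALSE, 12))
}

test_that("adjacency is row-stochastic with excluded self-edges", {
  params <- init_fusion_params(3)
  set.seed(1)
  H <- matrix(stats::rnorm(12 * 128), 12, 128)
  A <- build_adjacency(H, params)
  expect_equal(unname(rowSums(A)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(diag(A) == 0))
  # identical node features give uniform rows at 1/11
  H1 <- matrix(1, 12, 128)
  A1 <- build_adjacency(H1, params)
  off <- A1[row(A1) != col(A1)]
  expect_equal(off, rep(1 / 11, length(off)), tolerance = 1e-9)
})

test_that("permuting node order permutes the adjacency consistently", {
  params <- init_fusion_params(4)
  set.seed(2)
  H <- matrix(stats::rnorm(12 * 128), 12, 128)
  A <- build_adjacency(H, params)
  perm <- sample(12)
  A_perm <- build_adjacency(H[perm, ], params)
  expect_equal(A_perm, A[perm, perm], tolerance = 1e-9)
})

test_that("masking zeroes incident edges and renormalizes survivors", {
  params <- init_fusion_params(5)
  set.seed(3)
  H <- matrix(stats::rnorm(12 * 128), 12, 128)
  A <- build_adjacency(H, params)
  At <- mask_adjacency(A, c(video = TRUE, audio = FALSE, physio = TRUE))
  expect_true(all(At[5:8, ] == 0))
  expect_true(all(At[, 5:8] == 0))
  keep <- c(1:4, 9:12)
  expect_equal(unname(rowSums(At[keep, ])), rep(1, 8), tolerance = 1e-9)
  expect_identical(mask_adjacency(A, c(TRUE, TRUE, TRUE)), A)
  # only the physio block survives double masking
  At2 <- mask_adjacency(A, c(FALSE, FALSE, TRUE))
  expect_true(all(At2[1:8, ] == 0) && all(At2[, 1:8] == 0))
  expect_equal(unname(rowSums(At2[9:12, ])), rep(1, 4), tolerance = 1e-9)
  expect_equal(At2[9:12, 9:12],
               A[9:12, 9:12] / rowSums(A[9:12, 9:12]), tolerance = 1e-9)
  expect_np_error(mask_adjacency(A, c(FALSE, FALSE, FALSE)),
                  "np_empty_graph_error")
})

test_that("propagation matches a dense oracle and degenerates correctly", {
  params <- init_fusion_params(6)
  set.seed(4)
  H <- matrix(stats::rnorm(12 * 128), 12, 128)
  A <- build_adjacency(H, params)
  M <- stats::plogis(params$gates_G)
  diag(M) <- 0
  out <- propagate_and_pool(H, A, M, params)
  # independent dense-matrix oracle of the same two-layer update
  oracle <- {
    Aeff <- A * M
    relu <- function(x) pmax(x, 0)
    H1 <- relu(H %*% params$sage_W1s + (Aeff %*% H) %*% params$sage_W1n +
                 matrix(params$sage_b1, 12, 128, byrow = TRUE))
    H2 <- relu(H1 %*% params$sage_W2s + (Aeff %*% H1) %*% params$sage_W2n +
                 matrix(params$sage_b2, 12, 128, byrow = TRUE))
    colMeans(H2)
  }
  expect_equal(out$h_gnn, oracle, tolerance = 1e-6)

  # zero adjacency reduces to a per-node feed-forward network
  out0 <- propagate_and_pool(H, matrix(0, 12, 12), M, params)
  relu <- function(x) pmax(x, 0)
  ff <- relu(relu(H %*% params$sage_W1s +
                    matrix(params$sage_b1, 12, 128, byrow = TRUE)) %*%
               params$sage_W2s + matrix(params$sage_b2, 12, 128, byrow = TRUE))
  expect_equal(out0$h_gnn, colMeans(ff), tolerance = 1e-9)

  # single unmasked node: pooled output equals its two-layer self-transform
  mask1 <- c(TRUE, rep(FALSE, 11))
  out1 <- propagate_and_pool(H, mask_adjacency(A, rep(TRUE, 12) & mask1),
                             M, params, node_mask = mask1)
  h1 <- relu(H[1, , drop = FALSE] %*% params$sage_W1s +
               matrix(params$sage_b1, 1, 128))
  h2 <- relu(h1 %*% params$sage_W2s + matrix(params$sage_b2, 1, 128))
  expect_equal(out1$h_gnn, as.numeric(h2), tolerance = 1e-9)
})

test_that("evidential head implements the ReLU-plus-one Dirichlet map", {
  params <- init_fusion_params(7)
  params$ev_W <- matrix(0, 4, 128)
  params$ev_b <- numeric(4)
  ev <- evidential_forward(stats::rnorm(128), params)
  expect_equal(ev$alpha, rep(1, 4))
  expect_equal(ev$u, 1)
  expect_equal(ev$p, rep(0.25, 4))
  # evidence (8,0,0,0)
  params$ev_b <- c(8, 0, 0, 0)
  ev <- evidential_forward(numeric(128), params)
  expect_equal(ev$alpha, c(9, 1, 1, 1))
  expect_equal(ev$u, 1 / 3, tolerance = 1e-12)
  expect_equal(ev$p, c(0.75, 1 / 12, 1 / 12, 1 / 12), tolerance = 1e-12)
  # increasing any single evidence strictly decreases u
  for (k in 1:4) {
    params$ev_b <- numeric(4)
    u0 <- evidential_forward(numeric(128), params)$u
    params$ev_b[k] <- 2
    expect_lt(evidential_forward(numeric(128), params)$u, u0)
  }
})

test_that("evidential invariants hold for arbitrary finite head inputs", {
  set.seed(11)
  params <- init_fusion_params(8)
  for (i in 1:50) {
    params$ev_W <- matrix(stats::rnorm(4 * 128, 0, i / 10), 4, 128)
    params$ev_b <- stats::rnorm(4, 0, 5)
    ev <- evidential_forward(stats::rnorm(128, 0, 3), params)
    expect_true(all(ev$alpha >= 1))
    expect_equal(sum(ev$p), 1, tolerance = 1e-9)
    expect_equal(ev$u, 4 / sum(ev$alpha), tolerance = 1e-12)
    expect_identical(ev$u == 1, all(ev$alpha == 1))
    expect_true(ev$u > 0 && ev$u <= 1)
  }
})

test_that("prediction abstains above tau and breaks ties toward severity", {
  mk <- function(p, u) structure(list(p = p, u = u), class = "np_evidential")
  r <- predict_or_abstain(mk(rep(0.25, 4), 0.6), tau = 0.5)
  expect_true(r$abstain)
  r <- predict_or_abstain(mk(c(0.1, 0.2, 0.6, 0.1), 0.2), tau = 0.5)
  expect_false(r$abstain)
  expect_identical(r$level, 2L)
  r <- predict_or_abstain(mk(c(0.5, 0.5, 0, 0), 0.3), tau = 0.5)
  expect_identical(r$level, 1L)
  expect_true(r$tie)
})

test_that("fusion backward matches finite differences", {
  set.seed(13)
  params <- init_fusion_params(9)
  # keep all evidence logits strictly positive: the backward pass uses a
  # leaky subgradient through the evidence ReLU for dead units, which only
  # coincides with the finite-difference derivative on the active side
  params$ev_b <- rep(0.5, 4)
  cv <- random_cv(14, avail = c(rep(TRUE, 11), FALSE))
  fw0 <- fusion_forward(cv, params)
  expect_true(all(fw0$ev$logits > 0))
  w <- loss_weights()
  f_of <- function(p) {
    fw <- fusion_forward(cv, p)
    w$beta * loss_ordinal(fw$ev$alpha, 2)$value +
      w$gamma * loss_evidential(fw$ev$alpha, 2)$value +
      w$delta * loss_sparsity(fw$Aeff)$value
  }
  sl <- neopain:::sample_loss_grad(cv, 2, params, w, 1)
  eps <- 1e-6
  for (k in c("ev_W", "sage_W1n", "sage_W2s", "gates_G", "delta_A")) {
    for (r in 1:4) {
      i <- sample(length(params[[k]]), 1)
      p2 <- params; p2[[k]][i] <- p2[[k]][i] + eps
      p3 <- params; p3[[k]][i] <- p3[[k]][i] - eps
      fd <- (f_of(p2) - f_of(p3)) / (2 * eps)
      expect_equal(sl$grads[[k]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("assessments are invariant to audio content when audio is masked", {
  out <- fixture_episode(level = 2, seed = 77)
  ep <- out$episode
  mod <- small_model()
  strip_audio <- function(e, new_audio) {
    episode(e$meta, audio = new_audio, physio = e$physio, facial = e$facial)
  }
  base <- episode(ep$meta, physio = ep$physio, facial = ep$facial)
  ref <- assess_episode(base, model = mod)
  set.seed(99)
  for (i in 1:50) {
    # arbitrary replacement audio, then masked away: bit-identical result
    noisy <- strip_audio(ep, stats::runif(160000, -1, 1))
    masked <- episode(noisy$meta, physio = noisy$physio,
                      facial = noisy$facial)
    got <- assess_episode(masked, model = mod)
    expect_identical(got$pain_level, ref$pain_level)
    expect_identical(got$u_final, ref$u_final)
    expect_identical(got$explanation, ref$explanation)
    expect_identical(got$fired_rule_ids, ref$fired_rule_ids)
  }
})

test_that("encoders emit 128-dim embeddings with exact zeros when absent", {
  enc <- init_encoder_params(21)
  out <- fixture_episode(level = 1, seed = 201)
  h <- encode_modalities(out$episode, enc)
  expect_length(h$h_v, 128)
  expect_length(h$h_a, 128)
  expect_length(h$h_p, 128)
  no_audio <- episode(out$episode$meta, physio = out$episode$physio,
                      facial = out$episode$facial)
  h2 <- encode_modalities(no_audio, enc)
  expect_identical(h2$h_a, numeric(128))
  # determinism in evaluation mode
  h3 <- encode_modalities(out$episode, enc)
  expect_identical(h$h_a, h3$h_a)
  expect_identical(h$h_p, h3$h_p)
})

test_that("model parameters survive a save/load round trip", {
  params <- init_fusion_params(31)
  path <- withr::local_tempfile(fileext = ".json")
  params_save(params, path)
  back <- params_load(path)
  for (k in names(params)) {
    expect_equal(back[[k]], unclass(params[[k]]), tolerance = 1e-12,
                 ignore_attr = FALSE)
  }
})
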