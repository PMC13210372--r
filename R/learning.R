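# Supervised training of the fusion pipeline, MAML-style per-infant
# personalization, and the multi-task component losses.

# Parameters updated by supervised training. Encoders, concept-node
# embeddings and the adjacency MLP act as fixed random feature maps at desk
# scale; the graph gates, GraphSAGE weights and evidential head are learned.
TRAINABLE <- c("sage_W1s", "sage_W1n", "sage_b1", "sage_W2s", "sage_W2n",
               "sage_b2", "gates_G", "ev_W", "ev_b")

# Loss + gradient for one sample through the fusion path.
sample_loss_grad <- function(cv, y, params, weights, lambda_kl = 1,
                             modality_mask = NULL) {
  fw <- fusion_forward(cv, params, modality_mask)
  le <- loss_evidential(fw$ev$alpha, y, lambda_kl)
  lo <- loss_ordinal(fw$ev$alpha, y)
  ls <- loss_sparsity(fw$Aeff)
  dalpha <- weights$gamma * le$grad + weights$beta * lo$grad
  g <- fusion_backward(fw, params, dalpha,
                       dAeff_extra = weights$delta * ls$grad)
  list(value = weights$beta * lo$value + weights$gamma * le$value +
         weights$delta * ls$value,
       grads = g, ev = fw$ev)
}

#' Training configuration for the supervised pipeline
#'
#' Mirrors the full-scale recipe (cosine-annealed learning rate, batch 32,
#' KL annealing over the first 10 epochs) at desk-scale sizes.
#'
#' @param epochs training epochs
#' @param lr initial learning rate (cosine-annealed to 0)
#' @param batch minibatch size
#' @param modality_dropout probability of hiding one present modality of a
#'   training clip (missing-modality robustness; also calibrates the
#'   uncertainty elevation on masked inputs)
#' @param anneal_epochs KL annealing horizon for the evidential loss
#' @param weights a [loss_weights()]
#' @param seed RNG seed for shuffling and dropout
#' @return list of settings
#' @export
train_config <- function(epochs = 60L, lr = 0.3, batch = 32L,
                         modality_dropout = 0.15, anneal_epochs = 10L,
                         weights = loss_weights(), seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
       modality_dropout = modality_dropout,
       anneal_epochs = as.integer(anneal_epochs), weights = weights,
       seed = as.integer(seed))
}

#' Train the fusion pipeline on concept vectors
#'
#' Minibatch SGD with a cosine-annealed learning rate on the graph gates,
#' GraphSAGE weights and evidential head, minimizing the weighted ordinal +
#' evidential + sparsity objective.
#'
#' @param features list of `np_concept_vector`
#' @param labels integer pain levels 0..3 (same length)
#' @param params initial parameters (default fresh [init_fusion_params()])
#' @param config a [train_config()]
#' @return object of class `np_model`: `params`, `config`, `history`
#' @export
train_pipeline <- function(features, labels, params = init_fusion_params(),
                           config = train_config()) {
  stopifnot(length(features) == length(labels))
  if (any(!labels %in% 0:3))
    np_stop("np_validation_error", "pain labels must be in 0..3")
  n <- length(features)
  w <- config$weights
  history <- data.frame(epoch = integer(), loss = numeric())
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr_t <- config$lr * 0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
      lambda <- min(1, ep / config$anneal_epochs)
      idx <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = config$batch)) {
        bidx <- idx[b0:min(b0 + config$batch - 1, n)]
        acc <- NULL
        for (i in bidx) {
          mm <- NULL
          cvi <- features[[i]]
          present <- c(video = any(cvi$available[1:4]),
                       audio = any(cvi$available[5:8]),
                       physio = any(cvi$available[9:12]))
          if (sum(present) > 1 &&
              stats::runif(1) < config$modality_dropout) {
            drop <- sample(which(present), 1)
            mm <- present
            mm[drop] <- FALSE
          }
          sl <- sample_loss_grad(cvi, labels[i], params, w, lambda, mm)
          ep_loss <- ep_loss + sl$value
          if (is.null(acc)) {
            acc <- sl$grads
          } else {
            for (k in names(acc)) acc[[k]] <- acc[[k]] + sl$grads[[k]]
          }
        }
        for (k in TRAINABLE) {
          params[[k]] <- params[[k]] - lr_t * acc[[k]] / length(bidx)
        }
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n))
    }
  })
  structure(list(params = params, config = config, history = history),
            class = "np_model")
}

model_params <- function(model) {
  if (inherits(model, "np_model")) model$params else model
}

#' Predict pain levels (or abstentions) for a set of concept vectors
#'
#' @param model an `np_model` or parameter list
#' @param features list of `np_concept_vector`
#' @param tau abstention threshold on the epistemic uncertainty
#' @param modality_mask optional 3-boolean mask applied to every clip
#' @return data.frame: `level` (NA when abstained), `abstain`, `u`, `tie`
#' @export
predict_pipeline <- function(model, features, tau = 0.5,
                             modality_mask = NULL) {
  params <- model_params(model)
  out <- lapply(features, function(cv) {
    fw <- fusion_forward(cv, params, modality_mask)
    pa <- predict_or_abstain(fw$ev, tau)
    data.frame(level = pa$level, abstain = pa$abstain, u = pa$u, tie = pa$tie)
  })
  do.call(rbind, out)
}

#' Few-shot personalization (MAML inner loop)
#'
#' Applies `steps` gradient steps on the support loss to the per-infant
#' adjacency offset `delta_A` and the evidential head ONLY; concept heads,
#' encoders, embeddings and graph weights are bit-identical before and after.
#'
#' @param model an `np_model` or parameter list
#' @param support list with `features` (concept vectors) and `labels`
#' @param inner_lr inner-loop learning rate (default 0.01)
#' @param steps number of gradient steps (default 1)
#' @param weights a [loss_weights()]
#' @return parameter list with adapted `delta_A`, `ev_W`, `ev_b`
#' @export
maml_adapt <- function(model, support, inner_lr = 0.01, steps = 1L,
                       weights = loss_weights()) {
  params <- model_params(model)
  if (length(support$features) == 0)
    np_stop("np_validation_error", "support set is empty")
  for (s in seq_len(steps)) {
    acc <- NULL
    for (i in seq_along(support$features)) {
      sl <- sample_loss_grad(support$features[[i]], support$labels[i],
                             params, weights)
      if (is.null(acc)) acc <- sl$grads
      else for (k in ADAPTABLE) acc[[k]] <- acc[[k]] + sl$grads[[k]]
    }
    for (k in ADAPTABLE) {
      params[[k]] <- params[[k]] - inner_lr * acc[[k]] / length(support$features)
    }
  }
  params
}

#' Construct a meta-learning task
#'
#' @param infant_id infant identifier
#' @param support,query lists with `features`, `labels`, `clip_ids`
#' @return object of class `np_meta_task`
#' @export
meta_task <- function(infant_id, support, query) {
  if (length(intersect(support$clip_ids, query$clip_ids)) > 0)
    np_stop("np_leakage_error",
            "support and query clips overlap for infant %s", infant_id)
  structure(list(infant_id = infant_id, support = support, query = query),
            class = "np_meta_task")
}

#' First-order meta-training over per-infant tasks
#'
#' For each task, adapts on the support set ([maml_adapt()]) and accumulates
#' the query-loss gradient at the adapted point (first-order MAML); the outer
#' update moves the shared initialization of the adaptable parameters.
#' Infant-disjointness violations raise a leakage error rather than
#' proceeding.
#'
#' @param model an `np_model` or parameter list
#' @param tasks list of [meta_task()] objects
#' @param outer_lr outer-loop learning rate (default 0.001)
#' @param inner_lr,steps inner-loop settings
#' @param eval_infants infant ids reserved for evaluation; any task touching
#'   one raises a leakage error
#' @param weights a [loss_weights()]
#' @return parameter list with updated shared initialization
#' @export
meta_train <- function(model, tasks, outer_lr = 0.001, inner_lr = 0.01,
                       steps = 1L, eval_infants = character(),
                       weights = loss_weights()) {
  params <- model_params(model)
  task_infants <- vapply(tasks, function(t) t$infant_id, character(1))
  bad <- intersect(task_infants, eval_infants)
  if (length(bad) > 0)
    np_stop("np_leakage_error",
            "meta-training task cites evaluation infant(s): %s",
            paste(bad, collapse = ", "))
  acc <- NULL
  for (task in tasks) {
    adapted <- maml_adapt(params, task$support, inner_lr, steps, weights)
    for (i in seq_along(task$query$features)) {
      sl <- sample_loss_grad(task$query$features[[i]], task$query$labels[i],
                             adapted, weights)
      if (is.null(acc)) acc <- sl$grads
      else for (k in ADAPTABLE) acc[[k]] <- acc[[k]] + sl$grads[[k]]
    }
  }
  n_q <- sum(vapply(tasks, function(t) length(t$query$features), numeric(1)))
  for (k in ADAPTABLE) params[[k]] <- params[[k]] - outer_lr * acc[[k]] / n_q
  params
}

#' Compute the six multi-task loss components on a batch
#'
#' @param batch list with `features` (concept vectors), `labels` (pain
#'   levels; required), optional `concept_labels` (n x 12, NA = unlabeled),
#'   optional `embeddings` (list of `h_v`/`h_a`/`h_p`), optional `tasks`
#'   (meta tasks), optional `projections` + `pair_index` + `temperature`
#' @param model an `np_model` or parameter list
#' @return named list: `concept`, `ordinal`, `evidential`, `sparsity`,
#'   `meta`, `contrast`
#' @export
component_losses <- function(batch, model) {
  params <- model_params(model)
  if (is.null(batch$labels))
    np_stop("np_validation_error",
            "supervised losses require pain labels in the batch")
  n <- length(batch$features)
  l_ord <- l_ev <- l_sp <- 0
  for (i in seq_len(n)) {
    fw <- fusion_forward(batch$features[[i]], params)
    l_ord <- l_ord + loss_ordinal(fw$ev$alpha, batch$labels[i])$value
    l_ev <- l_ev + loss_evidential(fw$ev$alpha, batch$labels[i])$value
    l_sp <- l_sp + loss_sparsity(fw$Aeff)$value
  }
  l_con <- 0
  if (!is.null(batch$concept_labels)) {
    if (is.null(batch$embeddings))
      np_stop("np_validation_error",
              "concept loss requires modality embeddings in the batch")
    head_params <- params[c("head_W_v", "head_W_a", "head_W_p",
                            "head_b_v", "head_b_a", "head_b_p")]
    names(head_params) <- sub("head_", "", names(head_params))
    vals <- vapply(seq_len(n), function(i) {
      hb <- batch$embeddings[[i]]
      ch <- concept_heads_forward(hb$h_v, hb$h_a, hb$h_p, head_params)
      loss_concept(ch$matrix, batch$concept_labels[i, ])
    }, numeric(1))
    l_con <- mean(vals)
  }
  l_meta <- 0
  if (!is.null(batch$tasks) && length(batch$tasks) > 0) {
    w <- loss_weights()
    qvals <- vapply(batch$tasks, function(task) {
      adapted <- maml_adapt(params, task$support)
      mean(vapply(seq_along(task$query$features), function(i) {
        fw <- fusion_forward(task$query$features[[i]], adapted)
        loss_evidential(fw$ev$alpha, task$query$labels[i])$value
      }, numeric(1)))
    }, numeric(1))
    l_meta <- mean(qvals)
  }
  l_contrast <- 0
  if (!is.null(batch$projections)) {
    l_contrast <- contrastive_loss(batch$projections, batch$pair_index,
                                   batch$temperature %||% 0.1)
  }
  list(concept = l_con, ordinal = l_ord / n, evidential = l_ev / n,
       sparsity = l_sp / n, meta = l_meta, contrast = l_contrast)
}
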