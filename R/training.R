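#' Supervised individual-fitting configuration
#'
#' Defaults follow the individual-participant fitting protocol: 90/5/5
#' train/validation/test split by list, Adam (learning rate 0.001, moment
#' decays 0.9/0.999), mini-batches of 32 trials, early stopping with patience
#' 5 epochs on validation loss.
#'
#' @param fractions Train/validation/test fractions (sum to 1).
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Trials per mini-batch.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Hard cap on epochs.
#' @param seed Seed for shuffling and splitting.
#' @return An object of class `ms_supervised_config`.
#' @export
supervised_config <- function(fractions = c(0.90, 0.05, 0.05), lr = 0.001,
                              beta1 = 0.9, beta2 = 0.999, batch_size = 32,
                              patience = 5, max_epochs = 200, seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(fractions = fractions, lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "ms_supervised_config")
}

#' Reinforcement-learning configuration
#'
#' Defaults follow the free-recall policy-optimization protocol: rewards +1
#' per correct recall, -1 per incorrect recall, -0.5 per repeat of an already
#' correctly recalled word; entropy coefficient 0.01, discount 0.99, PPO clip
#' 0.2; 50,000 iterations of 4 episodes each, checkpointing every 5,000
#' iterations (one epoch); evaluation on 10,000 fresh lists. Generalized
#' advantage estimation with `gae_lambda` (1 recovers plain discounted
#' returns) and `update_epochs` PPO passes per batch are exposed.
#'
#' @param L List length per episode.
#' @param N Vocabulary size episodes draw from.
#' @param reward_correct,reward_incorrect,reward_repeat Reward structure.
#' @param ent_coef Entropy bonus coefficient.
#' @param gamma Discount factor in `(0, 1]`.
#' @param clip PPO clip coefficient (`> 0`).
#' @param iterations Training iterations.
#' @param episodes_per_batch Episodes per update batch.
#' @param checkpoint_interval Iterations per epoch/checkpoint.
#' @param eval_lists Lists for final policy evaluation.
#' @param gae_lambda Generalized-advantage-estimation lambda.
#' @param update_epochs PPO optimization epochs per batch.
#' @param vf_coef Critic loss coefficient.
#' @param lr Adam learning rate at the start of training.
#' @param lr_final Learning rate at the last iteration (linear anneal;
#'   default `lr / 10`).
#' @param max_steps Decoding cap per episode; default `L + 2` (a small
#'   margin over the list length, analogous to the bounded retrieval
#'   attempts of the CMR simulation).
#' @param seed Base seed.
#' @return An object of class `ms_rl_config`.
#' @export
rl_config <- function(L = 16, N = NULL, reward_correct = 1,
                      reward_incorrect = -1, reward_repeat = -0.5,
                      ent_coef = 0.01, gamma = 0.99, clip = 0.2,
                      iterations = 50000, episodes_per_batch = 4,
                      checkpoint_interval = 5000, eval_lists = 10000,
                      gae_lambda = 0.95, update_epochs = 4, vf_coef = 0.5,
                      lr = 0.002, lr_final = lr / 10, max_steps = NULL, seed = 1) {
  if (clip <= 0) stop("clip must be > 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (min(iterations, episodes_per_batch, checkpoint_interval, eval_lists,
          update_epochs, L) < 1) stop("all counts must be >= 1")
  structure(list(L = as.integer(L), N = N,
                 reward_correct = reward_correct,
                 reward_incorrect = reward_incorrect,
                 reward_repeat = reward_repeat, ent_coef = ent_coef,
                 gamma = gamma, clip = clip,
                 iterations = as.integer(iterations),
                 episodes_per_batch = as.integer(episodes_per_batch),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 eval_lists = as.integer(eval_lists),
                 gae_lambda = gae_lambda,
                 update_epochs = as.integer(update_epochs), vf_coef = vf_coef,
                 lr = lr, lr_final = if (is.null(lr_final)) lr else lr_final,
                 max_steps = if (is.null(max_steps)) as.integer(L) + 2L else as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "ms_rl_config")
}

#' Split a dataset into train/validation/test parts
#'
#' Random partition at trial granularity (so no presented list appears in
#' more than one part): validation and test sizes are floors of their
#' fractions, the remainder goes to training. Errors if any part would be
#' empty.
#'
#' @param ds An `ms_dataset`.
#' @param fractions Train/validation/test fractions.
#' @param seed Seed for the permutation.
#' @return List of three `ms_dataset`s: `train`, `validation`, `test`.
#' @export
split_trials <- function(ds, fractions = c(0.90, 0.05, 0.05), seed = 1) {
  n <- length(ds$trials)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1) {
    need <- ceiling(1 / min(fractions[2:3]))
    stop("too few trials to split at these fractions; need at least ", need)
  }
  perm <- with_seed(seed, sample.int(n))
  take <- function(idx) dataset(ds$trials[idx], ds$wordpool)
  list(train = take(perm[seq_len(n_train)]),
       validation = take(perm[n_train + seq_len(n_val)]),
       test = take(perm[n_train + n_val + seq_len(n_test)]))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  if (length(model$frozen_emb_rows)) grads$emb[model$frozen_emb_rows, ] <- 0
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(model = model, state = state)
}

# encode a trial's recall as a teacher-forced action sequence (full-vocab
# actions: items verbatim, terminated by the end-of-sequence action)
trial_actions <- function(trial, N) {
  c(trial$recall, N + 1L)
}

ce_loss_batch <- function(model, trials, compute_grads = FALSE) {
  N <- model$config$vocab_size
  batch <- lapply(trials, function(t) {
    list(study = as.integer(t$study), actions = as.integer(trial_actions(t, N)))
  })
  s2s_ce_grad_cpp(model$params, unclass(model$config), batch, compute_grads)
}

#' Fit a model to recall sequences by teacher-forced cross-entropy
#'
#' Trains on the participant's literal output sequences (intrusions and
#' repeats kept verbatim, terminated by the end-of-sequence token) with Adam
#' mini-batches, early-stopping on validation loss, and returns the
#' best-validation parameters with the held-out test loss.
#'
#' @param model An `ms_seq2seq` built with `output_mode = "full_vocab"`.
#' @param splits List with `train`, `validation`, `test` datasets (see
#'   [split_trials()]).
#' @param config [supervised_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best checkpoint), `trajectory` (per-epoch train
#'   and validation loss), `test_loss`, `epochs`, `stopped_early`.
#' @export
train_supervised <- function(model, splits, config = supervised_config(),
                             verbose = FALSE) {
  if (model$config$output_mode != "full_vocab") {
    stop("supervised fitting requires full_vocab output mode (verbatim targets)")
  }
  adam <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- list()
  wait <- 0L
  stopped <- FALSE
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(length(splits$train$trials))
      tr_losses <- c()
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        b <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        res <- ce_loss_batch(model, splits$train$trials[b], compute_grads = TRUE)
        if (!is.finite(res$loss)) stop("non-finite training loss (diverged)")
        st <- adam_step(model, res$grads, adam, config$lr, config$beta1, config$beta2)
        model <- st$model; adam <- st$state
        tr_losses <- c(tr_losses, res$loss)
      }
      val <- ce_loss_batch(model, splits$validation$trials)$loss
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                  val_loss = val)
      if (verbose) message(sprintf("epoch %d train %.4f val %.4f", epoch,
                                   mean(tr_losses), val))
      if (val < best$loss - 1e-9) {
        best <- list(loss = val, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped <- TRUE; break }
      }
    }
  })
  model$params <- best$params
  test_loss <- ce_loss_batch(model, splits$test$trials)$loss
  list(model = model, trajectory = do.call(rbind, hist), test_loss = test_loss,
       epochs = length(hist), best_epoch = best$epoch, stopped_early = stopped)
}

#' Score a recall sequence under the free-recall reward structure
#'
#' First correct recall of a studied item: `reward_correct` (+1); item not on
#' the list: `reward_incorrect` (-1); repeat of an already correctly recalled
#' item: `reward_repeat` (-0.5); the end-of-sequence step scores 0.
#'
#' @param study Study list.
#' @param recall Recalled item indices (end marker excluded).
#' @param rl [rl_config()] supplying the reward values.
#' @param ended Logical: did the sequence terminate with the end-of-sequence
#'   token (adds a 0-reward terminal step)?
#' @return List with `total` and `per_step` rewards.
#' @export
episode_reward <- function(study, recall, rl = rl_config(L = length(study)),
                           ended = FALSE) {
  labels <- classify_recalls(list(study = study_list(study, max(c(study, recall, 2L))),
                                  recall = as.integer(recall)))
  r <- vapply(labels, function(l) switch(l,
    "correct-first" = rl$reward_correct,
    "repeat" = rl$reward_repeat,
    "intrusion" = rl$reward_incorrect), numeric(1))
  if (ended) r <- c(r, 0)
  list(total = sum(r), per_step = unname(r))
}

#' Generalized advantage estimation
#'
#' Computes discounted returns and GAE advantages from per-step rewards and
#' value estimates (terminal value 0). With `lambda = 1` the advantages are
#' plain discounted returns minus values.
#'
#' @param rewards,values Equal-length numeric vectors.
#' @param gamma Discount factor.
#' @param lambda GAE lambda.
#' @return List with `adv` and `ret` (the return targets `adv + values`).
#' @export
gae <- function(rewards, values, gamma = 0.99, lambda = 0.95) {
  T <- length(rewards)
  adv <- numeric(T)
  last <- 0
  for (t in rev(seq_len(T))) {
    next_v <- if (t == T) 0 else values[t + 1L]
    delta <- rewards[t] + gamma * next_v - values[t]
    last <- delta + gamma * lambda * last
    adv[t] <- last
  }
  list(adv = adv, ret = adv + values)
}

#' Run one free-recall episode under the current policy
#'
#' Samples a fresh study list without replacement from the vocabulary, rolls
#' out the policy in sample mode, and records actions, log-probabilities,
#' value estimates, and per-step rewards.
#'
#' @param model An `ms_seq2seq` (full-vocab output mode).
#' @param rl [rl_config()].
#' @return List with `study`, `actions` (action indices; `N + 1` is the
#'   end-of-sequence action), `recall`, `rewards`, `logp`, `value`, `ended`,
#'   `total_reward`.
#' @export
run_episode <- function(model, rl) {
  N <- model$config$vocab_size
  study <- sample.int(N, rl$L)
  r <- s2s_rollout_cpp(model$params, unclass(model$config), study, 1L,
                       rl$max_steps, integer(0), FALSE)
  acts <- r$actions
  ended <- length(acts) > 0 && acts[length(acts)] == N + 1L
  recall <- acts[acts != N + 1L]
  rew <- episode_reward(study, recall, rl, ended = ended)
  list(study = study, actions = acts, recall = recall,
       rewards = rew$per_step, logp = r$logp, value = r$value,
       ended = ended, total_reward = rew$total)
}

#' One PPO update on a batch of episodes
#'
#' Computes GAE advantages (standardized across the batch), then performs
#' `rl$update_epochs` passes of the clipped-surrogate policy loss with
#' entropy bonus and value regression, applying Adam after each pass.
#'
#' @param model An `ms_seq2seq`.
#' @param episodes List of episode records from [run_episode()].
#' @param rl [rl_config()].
#' @param adam Adam state from [adam_init()] (created if `NULL`).
#' @return List with the updated `model`, `adam`, and a `losses` row
#'   (actor/critic loss, entropy).
#' @export
ppo_update <- function(model, episodes, rl, adam = NULL) {
  if (!length(episodes)) stop("empty batch")
  if (is.null(adam)) adam <- adam_init(model$params)
  batch <- lapply(episodes, function(e) {
    g <- gae(e$rewards, e$value, rl$gamma, rl$gae_lambda)
    list(study = as.integer(e$study), actions = as.integer(e$actions),
         adv = g$adv, ret = g$ret, oldlogp = e$logp)
  })
  all_adv <- unlist(lapply(batch, `[[`, "adv"))
  mu <- mean(all_adv)
  sdv <- stats::sd(all_adv)
  if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1
  batch <- lapply(batch, function(b) { b$adv <- (b$adv - mu) / sdv; b })
  losses <- NULL
  for (k in seq_len(rl$update_epochs)) {
    res <- s2s_ppo_grad_cpp(model$params, unclass(model$config), batch,
                            rl$clip, rl$ent_coef, rl$vf_coef)
    if (!is.finite(res$loss)) stop("non-finite PPO loss (diverged)")
    st <- adam_step(model, res$grads, adam, rl$lr)
    model <- st$model; adam <- st$state
    if (is.null(losses)) {
      losses <- data.frame(actor_loss = res$actor_loss,
                           critic_loss = res$critic_loss,
                           entropy = res$entropy)
    }
  }
  list(model = model, adam = adam, losses = losses)
}

#' Train a free-recall policy with PPO
#'
#' Runs the full loop: per iteration, `episodes_per_batch` fresh-list
#' episodes and one [ppo_update()]; every `checkpoint_interval` iterations
#' (one epoch) the parameters, optimizer and RNG state are checkpointed and
#' the mean episode reward logged, with optional behavioural-curve
#' evaluation. Epoch 0 is the initialized, untrained model. Interrupted runs
#' resume from the last checkpoint and reproduce the uninterrupted seeded
#' trajectory.
#'
#' @param rl [rl_config()] (field `N` gives the vocabulary size).
#' @param model_config [seq2seq_config()]; must use full-vocab output mode.
#' @param eval_per_epoch Number of fresh lists for per-epoch behavioural
#'   evaluation (0 disables).
#' @param resume A trajectory returned by an earlier, interrupted call (see
#'   `until`) to continue from its last checkpoint.
#' @param until Optional iteration to stop after (at most
#'   `rl$iterations`); the run can later be resumed to the full horizon
#'   and reproduces the uninterrupted seeded trajectory exactly.
#' @param verbose Print per-epoch summaries.
#' @return A training trajectory: list with `model` (final), `epochs` (data
#'   frame of per-epoch reward and losses), `checkpoints` (list of parameter
#'   snapshots with provenance), `curves` (per-epoch `ms_curves` when
#'   evaluated), `rl`, `model_config`.
#' @export
train_rl <- function(rl, model_config, eval_per_epoch = 0, resume = NULL,
                     until = NULL, verbose = FALSE) {
  if (is.null(rl$N)) stop("rl_config$N (vocabulary size) is required")
  if (model_config$output_mode != "full_vocab") {
    stop("reinforcement learning requires full_vocab output mode")
  }
  pool <- make_wordpool(rl$N, model_config$embed_dim, seed = rl$seed)
  if (is.null(resume)) {
    model <- build_model(model_config, pool)
    adam <- adam_init(model$params)
    set.seed(rl$seed)
    start_iter <- 0L
    epochs <- list()
    checkpoints <- list(list(epoch = 0L, iter = 0L, params = model$params))
    curves <- list()
    reward_acc <- c(); actor_acc <- c(); critic_acc <- c(); ent_acc <- c()
  } else {
    ck <- resume$checkpoints[[length(resume$checkpoints)]]
    model <- resume$model
    model$params <- ck$params
    adam <- ck$adam
    assign(".Random.seed", ck$rng, envir = globalenv())
    start_iter <- ck$iter
    epochs <- resume$epoch_rows
    checkpoints <- resume$checkpoints
    curves <- resume$curves
    reward_acc <- c(); actor_acc <- c(); critic_acc <- c(); ent_acc <- c()
  }
  eval_curves <- function(params) {
    m <- model; m$params <- params
    ev <- evaluate_policy(m, rl, n_lists = eval_per_epoch,
                          seed = rl$seed + 777L)
    ev
  }
  if (is.null(resume) && eval_per_epoch > 0) {
    curves[["0"]] <- eval_curves(model$params)
  }
  end_iter <- if (is.null(until)) rl$iterations else min(until, rl$iterations)
  rl_iter <- rl
  for (iter in (start_iter + 1L):end_iter) {
    # linear learning-rate anneal from lr to lr_final across the run
    frac <- if (rl$iterations > 1L) (iter - 1) / (rl$iterations - 1) else 0
    rl_iter$lr <- rl$lr + (rl$lr_final - rl$lr) * frac
    episodes <- lapply(seq_len(rl$episodes_per_batch),
                       function(i) run_episode(model, rl_iter))
    upd <- ppo_update(model, episodes, rl_iter, adam)
    model <- upd$model; adam <- upd$adam
    reward_acc <- c(reward_acc, mean(vapply(episodes, `[[`, numeric(1), "total_reward")))
    actor_acc <- c(actor_acc, upd$losses$actor_loss)
    critic_acc <- c(critic_acc, upd$losses$critic_loss)
    ent_acc <- c(ent_acc, upd$losses$entropy)
    if (iter %% rl$checkpoint_interval == 0L) {
      epoch <- iter %/% rl$checkpoint_interval
      epochs[[length(epochs) + 1L]] <- data.frame(
        epoch = epoch, iter = iter, mean_reward = mean(reward_acc),
        actor_loss = mean(actor_acc), critic_loss = mean(critic_acc),
        entropy = mean(ent_acc))
      checkpoints[[length(checkpoints) + 1L]] <-
        list(epoch = epoch, iter = iter, params = model$params, adam = adam,
             rng = get(".Random.seed", envir = globalenv()))
      if (eval_per_epoch > 0) curves[[as.character(epoch)]] <- eval_curves(model$params)
      if (verbose) message(sprintf("epoch %d (iter %d): mean reward %.3f",
                                   epoch, iter, mean(reward_acc)))
      reward_acc <- c(); actor_acc <- c(); critic_acc <- c(); ent_acc <- c()
    }
  }
  list(model = model, epochs = do.call(rbind, epochs), epoch_rows = epochs,
       checkpoints = checkpoints, curves = curves, rl = rl,
       model_config = model_config)
}

#' Evaluate a policy on freshly generated lists
#'
#' Generates `n_lists` study lists, rolls out the policy (sample mode),
#' and computes the behavioural curves, the mean episode reward, and the
#' mean recall probability (correctly recalled fraction of each list).
#'
#' @param model An `ms_seq2seq`.
#' @param rl [rl_config()].
#' @param n_lists Number of evaluation lists.
#' @param seed Seed for list generation and rollout sampling.
#' @param mode Rollout mode, `"sample"` (default) or `"greedy"`.
#' @return List with `curves` (`ms_curves`), `mean_reward`,
#'   `mean_recall_prob`, `trials`.
#' @export
evaluate_policy <- function(model, rl, n_lists = 10000, seed = 1,
                            mode = c("sample", "greedy")) {
  mode <- match.arg(mode)
  N <- model$config$vocab_size
  lists <- make_study_lists(N, rl$L, n_lists, seed = seed)
  acts <- with_seed(seed + 1L, {
    s2s_generate_many_cpp(model$params, unclass(model$config), lists,
                          if (mode == "sample") 1L else 0L, rl$max_steps)$actions
  })
  trials <- vector("list", n_lists)
  rewards <- recps <- numeric(n_lists)
  for (i in seq_len(n_lists)) {
    a <- acts[i, ]
    a <- a[a > 0L]
    ended <- length(a) > 0 && a[length(a)] == N + 1L
    recall <- a[a != N + 1L]
    trials[[i]] <- trial(lists[i, ], recall, participant = "rl",
                         session = as.character(i), N = N)
    rewards[i] <- episode_reward(lists[i, ], recall, rl, ended = ended)$total
    recps[i] <- length(unique(intersect(recall, lists[i, ]))) / rl$L
  }
  list(curves = behavioral_curves(trials), mean_reward = mean(rewards),
       mean_recall_prob = mean(recps), trials = trials)
}
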