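# Adversarial training of the two generators and two discriminators:
# forward cycle A -> B -> A and backward cycle B -> A -> B per step, the
# aleatoric (or plain) cycle-consistency loss, the gradient-consistency
# prior, and alternating generator/discriminator updates with Adam.
# Domain A is the MR-like modality, domain B the CT-like one; the
# discriminator of domain B therefore carries the "CT" adversarial term.

SCORE_EPS <- 1e-7

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.0002
#' and batch size 2, 200 epochs with the learning rate decaying linearly to
#' zero after the first 100, cycle weight `lambda = 10`, gradient-consistency
#' weight `gamma = 0.5`. Architecture sizes are exposed so experiments can be
#' scaled to the compute at hand.
#'
#' @param epochs total training epochs.
#' @param decay_start_epoch epoch after which the learning rate decays
#'   linearly to 0 at `epochs`.
#' @param lr initial Adam learning rate.
#' @param batch_size volumes per optimization step.
#' @param weights a [loss_weights()].
#' @param use_gc include the gradient-consistency term?
#' @param use_uncertainty model aleatoric uncertainty (2-channel generators
#'   and the aleatoric cycle loss) or not (1-channel, plain cycle loss)?
#' @param dropout_rate generator dropout probability.
#' @param seed master seed; fans out to weight init, patch sampling, dropout
#'   and the fake-volume pool, making the loss trajectory reproducible.
#' @param patch_shape training patch size (componentwise `<=` the volumes).
#' @param steps_per_epoch optimization steps per epoch; `NULL` (default)
#'   makes one pass over the smaller domain per epoch. With patch-based
#'   training an epoch is simply a fixed number of random patch draws, so
#'   this can exceed the dataset size.
#' @param pool_size size of the fake-volume history pool used for
#'   discriminator updates (0 disables pooling).
#' @param gen_depth,gen_base_filters generator U-Net size.
#' @param disc_n_layers,disc_base_filters discriminator size.
#' @return A `ucycle_train_config`.
#' @export
train_config <- function(epochs = 200, decay_start_epoch = 100, lr = 2e-4,
                         batch_size = 2, weights = loss_weights(),
                         use_gc = TRUE, use_uncertainty = TRUE,
                         dropout_rate = 0.2, seed = 1,
                         patch_shape = c(32, 32, 32), steps_per_epoch = NULL,
                         pool_size = 50,
                         gen_depth = 4, gen_base_filters = 16,
                         disc_n_layers = 3, disc_base_filters = 16) {
  if (decay_start_epoch > epochs) stopf("decay_start_epoch must be <= epochs")
  if (lr <= 0) stopf("lr must be positive")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  stopifnot(inherits(weights, "ucycle_loss_weights"))
  structure(list(epochs = as.integer(epochs),
                 decay_start_epoch = as.integer(decay_start_epoch),
                 lr = lr, batch_size = as.integer(batch_size),
                 weights = weights, use_gc = isTRUE(use_gc),
                 use_uncertainty = isTRUE(use_uncertainty),
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 patch_shape = as.integer(patch_shape),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                                   else as.integer(steps_per_epoch),
                 pool_size = as.integer(pool_size),
                 gen_depth = as.integer(gen_depth),
                 gen_base_filters = as.integer(gen_base_filters),
                 disc_n_layers = as.integer(disc_n_layers),
                 disc_base_filters = as.integer(disc_base_filters)),
            class = "ucycle_train_config")
}

#' Ablation modes
#'
#' The four combinations of the two model additions: the gradient-consistency
#' prior and the uncertainty head.
#'
#' @return Character vector of the four mode names.
#' @export
ablation_modes <- function() {
  c("withGC_withUnc", "withGC_withoutUnc", "withoutGC_withUnc",
    "withoutGC_withoutUnc")
}

#' Map an ablation mode name to config switches
#'
#' @param mode one of [ablation_modes()].
#' @return list with logicals `use_gc` and `use_uncertainty`.
#' @export
ablation_flags <- function(mode) {
  if (!mode %in% ablation_modes())
    stopf("unknown ablation mode '%s'", mode)
  list(use_gc = startsWith(mode, "withGC"),
       use_uncertainty = endsWith(mode, "_withUnc"))
}

#' Learning-rate schedule
#'
#' Constant through `decay_start_epoch`, then decaying linearly to 0 at
#' `epochs`.
#'
#' @param epoch epoch index in `[0, epochs]`.
#' @param cfg a [train_config()].
#' @return The learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(inherits(cfg, "ucycle_train_config"))
  if (epoch < 0 || epoch > cfg$epochs)
    stopf("epoch %s outside [0, %d]", format(epoch), cfg$epochs)
  if (epoch <= cfg$decay_start_epoch || cfg$decay_start_epoch == cfg$epochs)
    return(cfg$lr)
  cfg$lr * (cfg$epochs - epoch) / (cfg$epochs - cfg$decay_start_epoch)
}

# ---- fake-volume history pool ----------------------------------------------

new_pool <- function(size) {
  e <- new.env(parent = emptyenv())
  e$size <- as.integer(size)
  e$items <- list()
  e
}

pool_query <- function(pool, item) {
  if (pool$size == 0L) return(item)
  if (length(pool$items) < pool$size) {
    pool$items[[length(pool$items) + 1L]] <- item
    return(item)
  }
  if (stats::runif(1) < 0.5) {
    k <- sample.int(length(pool$items), 1L)
    old <- pool$items[[k]]
    pool$items[[k]] <- item
    old
  } else item
}

# ---- model container --------------------------------------------------------

#' Initialize the CycleGAN networks
#'
#' Builds both generators (with or without the uncertainty head, per
#' `cfg$use_uncertainty`), both discriminators, their Adam states and the
#' fake-volume pools. Weight initialization draws from the current RNG
#' stream. The returned environment is mutated in place by [train_step()].
#'
#' @param cfg a [train_config()].
#' @return An environment of class `ucycle_nets`.
#' @export
init_cyclegan <- function(cfg) {
  stopifnot(inherits(cfg, "ucycle_train_config"))
  gspec <- generator_spec(out_channels = if (cfg$use_uncertainty) 2 else 1,
                          depth = cfg$gen_depth,
                          base_filters = cfg$gen_base_filters,
                          dropout_rate = cfg$dropout_rate)
  dspec <- discriminator_spec(n_layers = cfg$disc_n_layers,
                              base_filters = cfg$disc_base_filters)
  e <- new.env(parent = emptyenv())
  e$g_ab <- build_generator(gspec)   # A (MR-like) -> B (CT-like)
  e$g_ba <- build_generator(gspec)   # B -> A
  e$d_a <- build_discriminator(dspec)
  e$d_b <- build_discriminator(dspec)
  e$opt_g_ab <- adam_init(e$g_ab$params)
  e$opt_g_ba <- adam_init(e$g_ba$params)
  e$opt_d_a <- adam_init(e$d_a$params)
  e$opt_d_b <- adam_init(e$d_b$params)
  e$pool_a <- new_pool(cfg$pool_size)  # fakes of domain A (syn MR)
  e$pool_b <- new_pool(cfg$pool_size)  # fakes of domain B (syn CT)
  e$epoch <- 0L
  class(e) <- "ucycle_nets"
  e
}

clamp_scores <- function(s) pmin(pmax(s, SCORE_EPS), 1 - SCORE_EPS)

#' One optimization step
#'
#' Executes the forward cycle (A -> B -> A) and backward cycle (B -> A -> B)
#' on one unpaired batch, updates both generators jointly against the full
#' objective (adversarial + weighted cycle term + weighted
#' gradient-consistency term), then updates both discriminators on real
#' versus pooled fake volumes from fresh forward passes (generators and
#' discriminators are never updated against the same computational pass).
#' Mutates `nets` in place.
#'
#' @param batch_a,batch_b lists of equal length holding [volume()]s or 3D
#'   arrays from the two domains (no pairing is assumed).
#' @param nets an [init_cyclegan()] environment.
#' @param cfg a [train_config()].
#' @param lr learning rate for this step (defaults to `cfg$lr`; [fit()]
#'   passes the scheduled value).
#' @return A `ucycle_loss_report` for the step.
#' @export
train_step <- function(batch_a, batch_b, nets, cfg, lr = cfg$lr) {
  stopifnot(inherits(nets, "ucycle_nets"), inherits(cfg, "ucycle_train_config"))
  B <- length(batch_a)
  if (B == 0L || length(batch_b) != B)
    stopf("batches must be non-empty and of equal length")
  lam <- cfg$weights$lambda_cycle
  gam <- cfg$weights$gamma_gc
  g_ab <- nets$g_ab; g_ba <- nets$g_ba
  grads_ab <- NULL; grads_ba <- NULL
  l_cycle_acc <- 0; l_gc_acc <- 0
  fakes_a <- vector("list", B); fakes_b <- vector("list", B)
  reals_a <- vector("list", B); reals_b <- vector("list", B)

  for (i in seq_len(B)) {
    x <- as_vol_array(batch_a[[i]])
    y <- as_vol_array(batch_b[[i]])
    reals_a[[i]] <- x; reals_b[[i]] <- y

    p1 <- generator_forward(g_ab, x, dropout_on = TRUE, want_cache = TRUE)
    p2 <- generator_forward(g_ba, p1$translation, dropout_on = TRUE, want_cache = TRUE)
    p3 <- generator_forward(g_ba, y, dropout_on = TRUE, want_cache = TRUE)
    p4 <- generator_forward(g_ab, p3$translation, dropout_on = TRUE, want_cache = TRUE)
    syn_b <- p1$translation; rec_a <- p2$translation
    syn_a <- p3$translation; rec_b <- p4$translation
    fakes_b[[i]] <- syn_b; fakes_a[[i]] <- syn_a

    # cycle term and its gradients
    if (cfg$use_uncertainty) {
      l_cyc_i <- aleatoric_cycle_loss(x, rec_a, p2$log_sigma,
                                      y, rec_b, p4$log_sigma)
      gx <- aleatoric_term_grads(x, rec_a, p2$log_sigma)
      gy <- aleatoric_term_grads(y, rec_b, p4$log_sigma)
      d_rec_a <- lam * gx$d_rec; d_ls_x <- lam * gx$d_log_sigma
      d_rec_b <- lam * gy$d_rec; d_ls_y <- lam * gy$d_log_sigma
    } else {
      l_cyc_i <- cycle_loss(x, rec_a, y, rec_b)
      d_rec_a <- lam * cycle_term_grad(x, rec_a); d_ls_x <- NULL
      d_rec_b <- lam * cycle_term_grad(y, rec_b); d_ls_y <- NULL
    }
    if (!is.finite(l_cyc_i))
      stopf("training diverged: non-finite cycle-consistency term")
    l_cycle_acc <- l_cycle_acc + l_cyc_i

    # backprop the recovering generators
    bw2 <- generator_backward(g_ba, p2$cache, d_rec_a, d_ls_x)
    bw4 <- generator_backward(g_ab, p4$cache, d_rec_b, d_ls_y)

    # adversarial gradients on the synthesized volumes (non-saturating)
    fb <- discriminator_forward(nets$d_b, syn_b, want_cache = TRUE)
    fa <- discriminator_forward(nets$d_a, syn_a, want_cache = TRUE)
    sb <- clamp_scores(fb$scores); sa <- clamp_scores(fa$scores)
    np_b <- length(sb); np_a <- length(sa)
    d_syn_b <- discriminator_backward(nets$d_b, fb$cache,
                                      array(-1 / (sb * np_b), dim(sb)))$dx
    d_syn_a <- discriminator_backward(nets$d_a, fa$cache,
                                      array(-1 / (sa * np_a), dim(sa)))$dx

    # gradient-consistency prior
    if (cfg$use_gc) {
      l_gc_i <- gc_loss(x, syn_b, y, syn_a)
      if (!is.finite(l_gc_i))
        stopf("training diverged: non-finite gradient-consistency term")
      l_gc_acc <- l_gc_acc + l_gc_i
      d_syn_b <- d_syn_b - gam * 0.5 * gradient_correlation_grad_b(x, syn_b)
      d_syn_a <- d_syn_a - gam * 0.5 * gradient_correlation_grad_b(y, syn_a)
    }

    d_syn_b <- d_syn_b + bw2$dx
    d_syn_a <- d_syn_a + bw4$dx
    bw1 <- generator_backward(g_ab, p1$cache, d_syn_b, NULL)
    bw3 <- generator_backward(g_ba, p3$cache, d_syn_a, NULL)

    grads_ab <- grads_add(grads_ab, grads_add(bw1$grads, bw4$grads))
    grads_ba <- grads_add(grads_ba, grads_add(bw2$grads, bw3$grads))
  }

  # joint generator update
  st <- adam_step(g_ab$params, grads_scale(grads_ab, 1 / B), nets$opt_g_ab, lr)
  nets$g_ab$params <- st$params; nets$opt_g_ab <- st$state
  st <- adam_step(g_ba$params, grads_scale(grads_ba, 1 / B), nets$opt_g_ba, lr)
  nets$g_ba$params <- st$params; nets$opt_g_ba <- st$state

  # discriminator updates on real vs pooled fake volumes (fresh passes)
  upd_disc <- function(disc_name, opt_name, pool, reals, fakes) {
    disc <- nets[[disc_name]]
    grads <- NULL
    obj <- 0
    for (i in seq_len(B)) {
      fake <- pool_query(pool, fakes[[i]])
      fr <- discriminator_forward(disc, reals[[i]], want_cache = TRUE)
      ff <- discriminator_forward(disc, fake, want_cache = TRUE)
      sr <- clamp_scores(fr$scores); sf <- clamp_scores(ff$scores)
      obj <- obj + mean(log(sr)) + mean(log(1 - sf))
      br <- discriminator_backward(disc, fr$cache,
                                   array(-1 / (sr * length(sr)), dim(sr)))
      bf <- discriminator_backward(disc, ff$cache,
                                   array(1 / ((1 - sf) * length(sf)), dim(sf)))
      grads <- grads_add(grads, grads_add(br$grads, bf$grads))
    }
    st <- adam_step(disc$params, grads_scale(grads, 1 / B), nets[[opt_name]], lr)
    nets[[disc_name]]$params <- st$params
    nets[[opt_name]] <- st$state
    obj / B  # the log-likelihood objective value (maximized by D)
  }
  l_adv_ct <- upd_disc("d_b", "opt_d_b", nets$pool_b, reals_b, fakes_b)
  l_adv_mr <- upd_disc("d_a", "opt_d_a", nets$pool_a, reals_a, fakes_a)

  report <- total_objective(l_adv_ct, l_adv_mr, l_cycle_acc / B,
                            l_gc = if (cfg$use_gc) l_gc_acc / B else NULL,
                            weights = cfg$weights, use_gc = cfg$use_gc)
  if (!is.finite(report$total))
    stopf("training diverged: non-finite total objective")
  report
}

# ---- checkpointing ----------------------------------------------------------

nets_to_list <- function(nets) {
  list(g_ab = nets$g_ab, g_ba = nets$g_ba, d_a = nets$d_a, d_b = nets$d_b,
       opt_g_ab = nets$opt_g_ab, opt_g_ba = nets$opt_g_ba,
       opt_d_a = nets$opt_d_a, opt_d_b = nets$opt_d_b,
       pool_a = nets$pool_a$items, pool_b = nets$pool_b$items,
       epoch = nets$epoch)
}

list_to_nets <- function(lst, cfg) {
  e <- init_cyclegan(cfg)
  for (nm in c("g_ab", "g_ba", "d_a", "d_b",
               "opt_g_ab", "opt_g_ba", "opt_d_a", "opt_d_b"))
    e[[nm]] <- lst[[nm]]
  e$pool_a$items <- lst$pool_a
  e$pool_b$items <- lst$pool_b
  e$epoch <- lst$epoch
  e
}

#' Load a training checkpoint
#'
#' @param path an `.rds` checkpoint written by [fit()].
#' @return A `ucycle_checkpoint` list with the networks, optimizer states,
#'   config, epoch counter and training log.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "ucycle_checkpoint"))
    stopf("%s is not a ucycle checkpoint", path)
  class(ck) <- "ucycle_checkpoint"
  ck
}

save_checkpoint <- function(nets, cfg, log, path) {
  ck <- c(nets_to_list(nets),
          list(cfg = cfg, log = log, format = "ucycle_checkpoint"))
  saveRDS(ck, path)
  invisible(path)
}

# ---- fit --------------------------------------------------------------------

#' Train the translation model
#'
#' Runs `cfg$epochs` epochs of [train_step()] over random patches of the two
#' unpaired volume sets. A fixed `cfg$seed` reproduces the loss trajectory
#' bit-for-bit on a fixed machine. When `out_dir` is given, a per-step CSV
#' training log (`training_log.csv`), the resolved config (`config.yaml`),
#' the last checkpoint and the best-by-total checkpoint are persisted there.
#'
#' @param dataset_a,dataset_b lists of [volume()]s for the two domains
#'   (at least one volume each).
#' @param cfg a [train_config()].
#' @param out_dir optional output directory.
#' @param resume_from optional checkpoint path or [load_checkpoint()] object;
#'   training continues from its epoch counter.
#' @return A `ucycle_fit`: list with the `nets` environment, `config`, the
#'   training `log` data frame and `out_dir`.
#' @export
fit <- function(dataset_a, dataset_b, cfg, out_dir = NULL, resume_from = NULL) {
  stopifnot(inherits(cfg, "ucycle_train_config"))
  if (length(dataset_a) < 1L || length(dataset_b) < 1L)
    stopf("each domain needs at least one volume")
  dataset_a <- lapply(dataset_a, function(v) if (is_volume(v)) v else volume(v))
  dataset_b <- lapply(dataset_b, function(v) if (is_volume(v)) v else volume(v))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  start_epoch <- 0L
  log <- data.frame()
  nets <- NULL
  if (!is.null(resume_from)) {
    ck <- if (inherits(resume_from, "ucycle_checkpoint")) resume_from
          else load_checkpoint(resume_from)
    nets <- list_to_nets(ck, cfg)
    start_epoch <- ck$epoch
    log <- ck$log
  }

  if (start_epoch >= cfg$epochs)
    return(structure(list(nets = nets, config = cfg, log = log,
                          out_dir = out_dir), class = "ucycle_fit"))

  with_seed(child_seed(cfg$seed, start_epoch), {
    if (is.null(nets)) nets <- init_cyclegan(cfg)
    n_steps <- cfg$steps_per_epoch %||%
      max(1L, min(length(dataset_a), length(dataset_b)) %/% cfg$batch_size)
    best_total <- if (nrow(log)) min(stats::aggregate(total ~ epoch, log, mean)$total) else Inf
    take_patch <- function(v) sample_patch(v, pmin(cfg$patch_shape, dim(v$data)))
    for (epoch in (start_epoch + 1L):cfg$epochs) {
      lr <- lr_schedule(epoch - 1L, cfg)
      ord_a <- sample.int(length(dataset_a))
      ord_b <- sample.int(length(dataset_b))
      epoch_tot <- 0
      for (step in seq_len(n_steps)) {
        pick <- function(ord, ds, j) ds[[ord[((j - 1L) %% length(ord)) + 1L]]]
        idx <- (step - 1L) * cfg$batch_size + seq_len(cfg$batch_size)
        batch_a <- lapply(idx, function(j) take_patch(pick(ord_a, dataset_a, j)))
        batch_b <- lapply(idx, function(j) take_patch(pick(ord_b, dataset_b, j)))
        rep_i <- train_step(batch_a, batch_b, nets, cfg, lr = lr)
        log <- rbind(log, data.frame(epoch = epoch, step = step,
                                     l_adv_ct = rep_i$l_adv_ct,
                                     l_adv_mr = rep_i$l_adv_mr,
                                     l_cycle = rep_i$l_cycle,
                                     l_gc = rep_i$l_gc,
                                     total = rep_i$total))
        epoch_tot <- epoch_tot + rep_i$total
      }
      nets$epoch <- epoch
      if (!is.null(out_dir)) {
        save_checkpoint(nets, cfg, log, file.path(out_dir, "checkpoint_last.rds"))
        if (epoch_tot / n_steps < best_total) {
          best_total <- epoch_tot / n_steps
          save_checkpoint(nets, cfg, log, file.path(out_dir, "checkpoint_best.rds"))
        }
        utils::write.csv(log, file.path(out_dir, "training_log.csv"),
                         row.names = FALSE)
        yaml::write_yaml(unclass_config(cfg), file.path(out_dir, "config.yaml"))
      }
    }
  })
  structure(list(nets = nets, config = cfg, log = log, out_dir = out_dir),
            class = "ucycle_fit")
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$weights <- unclass(out$weights)
  out
}

#' @export
print.ucycle_fit <- function(x, ...) {
  cat(sprintf("<ucycle_fit> %d epochs, final total %.4f (use_gc=%s, use_uncertainty=%s)\n",
              max(x$log$epoch), mean(x$log$total[x$log$epoch == max(x$log$epoch)]),
              x$config$use_gc, x$config$use_uncertainty))
  invisible(x)
}

#' Aleatoric tissue/bone contrast on a phantom
#'
#' Translates the CT-like modality of a phantom through the B -> A generator
#' with Monte-Carlo dropout and summarizes the mean aleatoric map over the
#' ground-truth soft-tissue and bone masks. Soft-tissue detail of the MR-like
#' modality is destroyed by the forward translation and cannot be recovered,
#' so a trained model should assign higher aleatoric uncertainty to tissue
#' than to bone (`contrast > 0`).
#'
#' @param model a `ucycle_fit`, `ucycle_nets` environment or checkpoint.
#' @param phantom a [make_phantom()] result (held out from training).
#' @param T Monte-Carlo samples.
#' @param seed seed for the dropout draws.
#' @return list with `tissue_mean`, `bone_mean`, `contrast`
#'   (= tissue - bone) and the [mc_translate()] `result`.
#' @export
evaluate_aleatoric_contrast <- function(model, phantom, T = 20, seed = 1) {
  stopifnot(inherits(phantom, "ucycle_phantom"))
  g_ba <- if (inherits(model, "ucycle_fit")) model$nets$g_ba
          else if (inherits(model, "ucycle_nets")) model$g_ba
          else if (inherits(model, "ucycle_checkpoint")) model$g_ba
          else stopf("model must be a ucycle_fit, ucycle_nets or checkpoint")
  if (g_ba$spec$out_channels != 2L)
    stopf("model was trained without the uncertainty head")
  mc <- mc_translate(g_ba, phantom$modality_b, T = T, seed = seed)
  tm <- mean(mc$aleatoric_mean[phantom$tissue_mask])
  bm <- mean(mc$aleatoric_mean[phantom$bone_mask])
  list(tissue_mean = tm, bone_mean = bm, contrast = tm - bm, result = mc)
}

#' Train all four ablation modes
#'
#' Trains `withGC_withUnc`, `withGC_withoutUnc`, `withoutGC_withUnc` and
#' `withoutGC_withoutUnc` with identical seeds and data, writing each run to
#' `out_dir/<mode>/`. Modes with the uncertainty head additionally emit
#' Monte-Carlo aleatoric/epistemic maps for the held-out phantoms and report
#' the tissue/bone aleatoric contrast.
#'
#' @param dataset_a,dataset_b unpaired training volumes per domain.
#' @param base_cfg a [train_config()]; `use_gc`/`use_uncertainty` are
#'   overridden per mode.
#' @param out_dir output directory; one subdirectory per mode.
#' @param heldout optional list of [make_phantom()] phantoms for the
#'   uncertainty evaluation.
#' @param T Monte-Carlo samples for the evaluation.
#' @return list of per-mode results (fit log tail, config flags, and for
#'   uncertainty modes the aleatoric contrasts), plus a `comparison` data
#'   frame.
#' @export
run_ablation <- function(dataset_a, dataset_b, base_cfg, out_dir,
                         heldout = NULL, T = 20) {
  stopifnot(inherits(base_cfg, "ucycle_train_config"))
  results <- list()
  for (mode in ablation_modes()) {
    flags <- ablation_flags(mode)
    cfg <- base_cfg
    cfg$use_gc <- flags$use_gc
    cfg$use_uncertainty <- flags$use_uncertainty
    mode_dir <- file.path(out_dir, mode)
    run <- fit(dataset_a, dataset_b, cfg, out_dir = mode_dir)
    entry <- list(mode = mode, use_gc = flags$use_gc,
                  use_uncertainty = flags$use_uncertainty,
                  final_total = mean(run$log$total[run$log$epoch == max(run$log$epoch)]))
    if (flags$use_uncertainty && length(heldout)) {
      contrasts <- vapply(seq_along(heldout), function(i) {
        ev <- evaluate_aleatoric_contrast(run, heldout[[i]], T = T,
                                          seed = child_seed(cfg$seed, i))
        write_mc_result(ev$result, mode_dir, prefix = sprintf("heldout%02d", i))
        ev$contrast
      }, numeric(1))
      entry$aleatoric_contrast <- contrasts
    }
    results[[mode]] <- entry
  }
  results$comparison <- do.call(rbind, lapply(ablation_modes(), function(m) {
    r <- results[[m]]
    data.frame(mode = m, use_gc = r$use_gc, use_uncertainty = r$use_uncertainty,
               final_total = r$final_total,
               mean_aleatoric_contrast =
                 if (is.null(r$aleatoric_contrast)) NA_real_
                 else mean(r$aleatoric_contrast))
  }))
  results
}
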