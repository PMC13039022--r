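# Training and evaluation entry points.
#
# Protocol defaults: Adam (lr 1e-4, beta1 0.9, beta2 0.999, eps 1e-8,
# weight decay 1e-5), batch size 1, 160 epochs, three replicate seeds
# (42, 57, 89) reported as mean +/- sample sd. Gradients are computed by
# the hand-written backward pass in net.R; the VQ commitment gradient is
# injected at the bottleneck (straight-through), the codebook-update
# gradient goes directly to the prototype matrix.

PARAM_LEAVES <- c("W", "b", "gamma", "beta", "W_a", "b_a", "W_b", "C_out")

# Recursively collect parameter paths ("enc.1.b1r.conv.W", ...) from a
# gradient tree or the network itself.
collect_param_paths <- function(x, prefix = character(0)) {
  out <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v) && !inherits(v, "net_config"))
      out <- c(out, collect_param_paths(v, c(prefix, nm)))
    else if (is.numeric(v) && nm %in% PARAM_LEAVES)
      out <- c(out, paste(c(prefix, nm), collapse = "."))
  }
  out
}

get_by_path <- function(x, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    i <- suppressWarnings(as.integer(p))
    x <- if (!is.na(i)) x[[i]] else x[[p]]
  }
  x
}

set_by_path <- function(x, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    i <- suppressWarnings(as.integer(parts))
    if (!is.na(i)) x[[i]] <- value else x[[parts]] <- value
    return(x)
  }
  head <- parts[1]
  i <- suppressWarnings(as.integer(head))
  key <- if (!is.na(i)) i else head
  x[[key]] <- set_by_path(x[[key]], paste(parts[-1], collapse = "."),
                          value)
  x
}

# Gradient trees use unnamed list indices for levels; name them so paths
# line up with the network structure.
name_levels <- function(g) {
  for (slot in c("enc", "dec")) {
    if (!is.null(g[[slot]]) && is.null(names(g[[slot]])))
      names(g[[slot]]) <- as.character(seq_along(g[[slot]]))
  }
  g
}

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(net, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  paths <- collect_param_paths(grads)
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (p in paths) {
    g <- get_by_path(grads, p)
    w <- get_by_path(net, p)
    if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * w
    m <- opt$m[[p]]
    v <- opt$v[[p]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    opt$m[[p]] <- m
    opt$v[[p]] <- v
    w <- w - cfg$lr * (m / corr1) / (sqrt(v / corr2) + cfg$eps)
    net <- set_by_path(net, p, w)
  }
  list(net = net, opt = opt)
}

#' Training configuration
#'
#' @param lr,beta1,beta2,eps,weight_decay Adam settings.
#' @param batch_size cases per optimization step (default 1).
#' @param epochs passes over the training cases.
#' @param seeds replicate seeds for [replicate_and_aggregate()].
#' @param net a [net_config()].
#' @param weights a [loss_weights()].
#' @param out_dir optional run directory for logs and checkpoints.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 1e-5, batch_size = 1L,
                         epochs = 160L, seeds = c(42L, 57L, 89L),
                         net = net_config(), weights = loss_weights(),
                         out_dir = NULL) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seeds = as.integer(seeds),
                 net = net, weights = weights, out_dir = out_dir),
            class = "train_config")
}

# Binary GT vectors (1 x N matrices) from an integer label array.
gt_from_mask <- function(mask) {
  m <- if (inherits(mask, "volume3d")) mask$data else mask
  list(liver = matrix(as.numeric(m >= 1), 1L),
       tumor = matrix(as.numeric(m == 2), 1L))
}

hard_dice <- function(p, g) {
  pb <- p > 0.5
  gb <- g > 0.5
  s <- sum(pb) + sum(gb)
  if (s == 0) return(1)
  2 * sum(pb & gb) / s
}

# One optimization step on one case; returns updated net/opt and the loss
# components.
train_step <- function(net, opt, x, mask, cfg) {
  w <- cfg$weights
  out <- net_forward(net, x, train = TRUE)
  gt <- gt_from_mask(mask)
  lp <- as.numeric(sigmoid(out$liver_logit))
  tp <- as.numeric(sigmoid(out$tumor_logit))
  lg <- as.numeric(gt$liver)
  tg <- as.numeric(gt$tumor)

  seg <- segmentation_loss(lp, tp, lg, tg)
  g_liver <- seg_head_logit_grad(lp, lg)
  g_tumor <- seg_head_logit_grad(tp, tg)

  contain <- containment_loss(tp, lp)
  cg <- containment_grads(tp, lp)
  g_tumor <- g_tumor + w$beta * cg$gT * tp * (1 - tp)
  g_liver <- g_liver + w$beta * cg$gL * lp * (1 - lp)

  vq <- 0
  gZ_extra <- NULL
  gE <- NULL
  if (net$cfg$use_codebook) {
    aux <- out$cache$vq
    vq <- vq_loss(aux$Z, aux$Z_q, w$lambda_vq)
    vg <- vq_loss_grads(aux$Z, aux$Z_q, aux$indices, net$cfg$codebook_K,
                        w$lambda_vq)
    gZ_extra <- w$alpha * vg$gZ
    gE <- w$alpha * vg$gE
  }
  total <- hybrid_loss(seg, vq, contain, w)
  if (!is.finite(total)) stop("non-finite loss")

  sd0 <- ft_sdim(out$liver_logit)
  grads <- net_backward(net, out$cache,
                        ft(matrix(g_liver, 1L), sd0),
                        ft(matrix(g_tumor, 1L), sd0),
                        gZ_extra = gZ_extra)
  grads <- name_levels(grads)
  net <- name_levels_net(net)
  st <- adam_step(net, grads, opt, cfg)
  net <- st$net
  opt <- st$opt
  if (!is.null(gE)) {
    opt$t_E <- (opt$t_E %||% 0L) + 1L
    g <- gE + cfg$weight_decay * net$E
    mE <- opt$mE %||% (g * 0)
    vE <- opt$vE %||% (g * 0)
    mE <- cfg$beta1 * mE + (1 - cfg$beta1) * g
    vE <- cfg$beta2 * vE + (1 - cfg$beta2) * g^2
    opt$mE <- mE; opt$vE <- vE
    E <- net$E - cfg$lr * (mE / (1 - cfg$beta1^opt$t_E)) /
      (sqrt(vE / (1 - cfg$beta2^opt$t_E)) + cfg$eps)
    class(E) <- class(net$E)
    net$E <- E
  }
  list(net = net, opt = opt, seg = seg, vq = vq, contain = contain,
       total = total,
       perplexity = if (!is.null(out$vq_aux)) out$vq_aux$perplexity
                    else NA_real_,
       liver_dice = hard_dice(lp, lg), tumor_dice = hard_dice(tp, tg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

name_levels_net <- function(net) {
  for (slot in c("enc", "dec"))
    if (is.null(names(net[[slot]])))
      names(net[[slot]]) <- as.character(seq_along(net[[slot]]))
  net
}

#' Train the segmentation network
#'
#' `data` is a list of cases, each a list with `image` (a [volume3d()] or a
#' 3D array, intensities already normalized to `[0, 1]`) and `mask`
#' (integer labels 0/1/2). One epoch is one pass over the cases with batch
#' size 1. Fully deterministic given `seed`.
#'
#' @param cfg a [train_config()].
#' @param data training cases.
#' @param val_data optional validation cases; the checkpoint with the best
#'   mean liver+tumor Dice is retained (otherwise the final state).
#' @param seed RNG seed for parameter initialization and case order.
#' @param max_steps optional hard cap on total optimization steps.
#' @param verbose print per-epoch summaries.
#' @return list of class `train_run`: `net` (best), `final_net`, `log`
#'   (per-step data.frame), `epoch_log`, `seed`, `cfg`.
#' @export
train <- function(cfg, data, val_data = NULL, seed = 42L, max_steps = NULL,
                  verbose = FALSE) {
  stopifnot(length(data) >= 1L)
  set.seed(seed)
  net <- build_net(cfg$net)
  net <- name_levels_net(net)
  opt <- adam_init()
  log <- list()
  epoch_log <- list()
  best <- list(score = -Inf, net = net)
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    epoch_first <- step + 1L
    ord <- if (length(data) > 1L) sample(length(data)) else 1L
    for (i in ord) {
      case <- data[[i]]
      x <- if (inherits(case$image, "volume3d")) case$image$data
           else case$image
      res <- tryCatch(train_step(net, opt, x, case$mask, cfg),
                      error = function(e)
                        stop("training aborted at epoch ", epoch, ", step ",
                             step + 1L, ": ", conditionMessage(e)))
      net <- res$net
      opt <- res$opt
      step <- step + 1L
      log[[step]] <- data.frame(epoch = epoch, step = step, seg = res$seg,
                                vq = res$vq, contain = res$contain,
                                total = res$total,
                                perplexity = res$perplexity,
                                liver_dice = res$liver_dice,
                                tumor_dice = res$tumor_dice)
      if (!is.null(max_steps) && step >= max_steps) { done <- TRUE; break }
    }
    el <- do.call(rbind, log[epoch_first:step])
    epoch_log[[epoch]] <- data.frame(epoch = epoch,
                                     seg = mean(el$seg), vq = mean(el$vq),
                                     contain = mean(el$contain),
                                     total = mean(el$total),
                                     perplexity = mean(el$perplexity))
    if (verbose)
      message(sprintf("epoch %d: total %.4f (seg %.4f vq %.4f cont %.5f)",
                      epoch, mean(el$total), mean(el$seg), mean(el$vq),
                      mean(el$contain)))
    if (!is.null(val_data)) {
      sc <- mean(vapply(val_data, function(case) {
        x <- if (inherits(case$image, "volume3d")) case$image$data
             else case$image
        o <- net_forward(net, x)
        g <- gt_from_mask(case$mask)
        (hard_dice(as.numeric(o$liver_prob), as.numeric(g$liver)) +
         hard_dice(as.numeric(o$tumor_prob), as.numeric(g$tumor))) / 2
      }, 0))
      if (sc > best$score) best <- list(score = sc, net = net)
    }
    if (done) break
  }
  if (is.null(val_data)) best <- list(score = NA_real_, net = net)
  run <- list(net = best$net, final_net = net, log = do.call(rbind, log),
              epoch_log = do.call(rbind, epoch_log), seed = seed, cfg = cfg)
  class(run) <- "train_run"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(run$log, file.path(cfg$out_dir,
                                 sprintf("log_seed%d.csv", seed)),
              row.names = FALSE)
    yaml::write_yaml(serialize_train_config(cfg),
                     file.path(cfg$out_dir, "config.yaml"))
    saveRDS(run, file.path(cfg$out_dir,
                           sprintf("checkpoint_seed%d.rds", seed)))
  }
  run
}

#' Segment a volume with a trained network
#'
#' @param net a trained `hepaseg_net`.
#' @param image volume (array or [volume3d()]) with intensities in `[0,1]`.
#' @param threshold probability threshold for the binary masks.
#' @return list with `liver`, `tumor` binary 3D arrays and the probability
#'   maps.
#' @export
predict_volume <- function(net, image, threshold = 0.5) {
  x <- if (inherits(image, "volume3d")) image$data else image
  o <- net_forward(net, x)
  d <- dim(x)
  lp <- array(as.numeric(o$liver_prob), d)
  tp <- array(as.numeric(o$tumor_prob), d)
  list(liver = lp > threshold, tumor = tp > threshold,
       liver_prob = lp, tumor_prob = tp)
}

#' Train and evaluate across replicate seeds, report mean +/- sd
#'
#' @param cfg a [train_config()].
#' @param data training cases (see [train()]).
#' @param test_data cases to evaluate.
#' @param seeds at least two seeds (default from `cfg`).
#' @param spacing voxel spacing for the surface metrics.
#' @param max_steps optional per-run step cap.
#' @return list with `per_seed` (metric data.frame per seed), `summary`
#'   (mean and sample sd per structure x metric) and `failed` seeds.
#' @export
replicate_and_aggregate <- function(cfg, data, test_data,
                                    seeds = cfg$seeds,
                                    spacing = c(1, 1, 1),
                                    max_steps = NULL) {
  stopifnot(length(seeds) >= 2L)
  per_seed <- list()
  failed <- integer(0)
  for (s in seeds) {
    res <- tryCatch({
      run <- train(cfg, data, seed = s, max_steps = max_steps)
      reps <- lapply(test_data, function(case) {
        pr <- predict_volume(run$net, case$image)
        m <- if (inherits(case$mask, "volume3d")) case$mask$data
             else case$mask
        metric_report(pr$liver, pr$tumor, m, spacing)
      })
      agg <- do.call(rbind, reps)
      cbind(seed = s, agg)
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, s)
    else per_seed[[as.character(s)]] <- res
  }
  all <- do.call(rbind, per_seed)
  metrics <- c("dice", "voe", "rvd", "asd_mm", "hd95_mm")
  summ <- do.call(rbind, lapply(unique(all$structure), function(st) {
    do.call(rbind, lapply(metrics, function(mt) {
      v <- all[all$structure == st, mt]
      data.frame(structure = st, metric = mt,
                 mean = mean(v, na.rm = TRUE),
                 sd = sd(v, na.rm = TRUE))
    }))
  }))
  list(per_seed = per_seed, summary = summ, failed = failed)
}

# --- config serialization (YAML round trip) --------------------------------

serialize_train_config <- function(cfg) {
  x <- unclass(cfg)
  x$net <- unclass(x$net)
  x$weights <- unclass(x$weights)
  x
}

#' Write a training configuration to YAML
#' @param cfg a [train_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_train_config <- function(cfg, path) {
  yaml::write_yaml(serialize_train_config(cfg), path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path a YAML file written by [write_train_config()].
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$net <- do.call(net_config, x$net)
  x$weights <- do.call(loss_weights, x$weights)
  do.call(train_config, x)
}
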