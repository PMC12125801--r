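# End-to-end orchestration: seeded phantom data -> preprocessing -> Dice
# training with Adam -> checkpointing -> seven-metric evaluation ->
# ablation grids with ANOVA/LSD comparison.

#' Training configuration
#'
#' Hyperparameter defaults (Adam, learning rate 1e-3, batch size 8) are
#' repository policy for phantom-scale runs and are all overridable.
#'
#' @param model A [model_config()].
#' @param loss A [dice_loss_spec()].
#' @param data Either a `phantom_dataset` from [generate_dataset()] or a
#'   list `(n = , base_spec = , jitter = )` describing one to generate.
#' @param window [window_spec()] applied to HU images before the model.
#' @param clahe Apply CLAHE after windowing.
#' @param augment Optional [augmentation_spec()] applied to training cases
#'   each epoch (`NULL` disables augmentation).
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate,batch_size,epochs Optimization schedule.
#' @param patience Early-stopping patience on validation Dice (epochs).
#' @param seed Master seed: fixed before any stochastic operation (data
#'   generation, weight init, batch shuffling).
#' @param checkpoint Path for the trained checkpoint (default: tempfile).
#' @return Object of class `train_config`.
#' @export
train_config <- function(model = model_config(), loss = dice_loss_spec(),
                         data = list(n = 30L), window = window_spec(),
                         clahe = FALSE, augment = NULL, optimizer = "adam",
                         learning_rate = 1e-3, batch_size = 8L, epochs = 50L,
                         patience = 10L, seed = 1L, checkpoint = NULL) {
  stopifnot(inherits(model, "model_config"), inherits(loss, "dice_loss_spec"),
            inherits(window, "window_spec"))
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  if (batch_size < 1L || epochs < 1L) {
    stop("batch_size and epochs must be positive")
  }
  if (is.null(checkpoint)) checkpoint <- tempfile(fileext = ".rds")
  structure(list(model = model, loss = loss, data = data, window = window,
                 clahe = clahe, augment = augment, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), checkpoint = checkpoint),
            class = "train_config")
}

resolve_dataset <- function(data, seed) {
  if (inherits(data, "phantom_dataset")) return(data)
  n <- if (!is.null(data$n)) data$n else 30L
  base_spec <- if (!is.null(data$base_spec)) data$base_spec else phantom_spec()
  generate_dataset(n, base_spec, jitter = data$jitter, seed = seed)
}

preprocess_pairs <- function(pairs, window, clahe) {
  lapply(pairs, function(p) {
    list(x = preprocess_slice(p$image, window, clahe), y = p$mask)
  })
}

stack_batch <- function(items, field) {
  d <- dim(items[[1L]][[field]])
  out <- array(0, c(d[1L], d[2L], 1L, length(items)))
  for (i in seq_along(items)) out[, , 1L, i] <- items[[i]][[field]]
  out
}

batch_val_dice <- function(model, items, threshold) {
  scores <- vapply(items, function(it) {
    pred <- predict_mask(model, it$x, threshold)
    ov <- overlap_metrics(it$y, pred)
    ov[["dsc"]]
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Train an MSAU-Net on phantom (or preloaded) data
#'
#' Deterministic under `cfg$seed` on one device: dataset generation,
#' weight initialization, shuffling and augmentation all derive from it.
#' Per-epoch mean training loss and validation Dice are logged; training
#' aborts with a diagnostic if the loss goes non-finite, and stops early
#' when validation Dice has not improved for `patience` epochs.
#'
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_result`: `model`, `log` (data frame with
#'   epoch, train_loss, val_dice), `checkpoint` path, `dataset`.
#' @export
run_training <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  dataset <- resolve_dataset(cfg$data, seeds[1L])
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "val")
  train_items <- preprocess_pairs(dataset$pairs[tr_idx], cfg$window, cfg$clahe)
  val_items <- preprocess_pairs(dataset$pairs[va_idx], cfg$window, cfg$clahe)

  model <- build_model(cfg$model, seed = seeds[2L])
  opt <- adam_init(model$params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric())
  best_dice <- -Inf
  best_epoch <- 0L
  epoch_seeds <- derive_seeds(seeds[3L], cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    items <- train_items
    if (!is.null(cfg$augment)) {
      aug_seeds <- derive_seeds(epoch_seeds[epoch] %% 1000000L + epoch, length(items))
      items <- lapply(seq_along(items), function(i) {
        a <- augment_pair(items[[i]]$x, items[[i]]$y, cfg$augment,
                          seed = aug_seeds[i])
        list(x = a$image, y = a$mask)
      })
    }
    ord <- with_seed(epoch_seeds[epoch], sample.int(length(items)))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      xb <- stack_batch(items[idx], "x")
      yb <- stack_batch(items[idx], "y")
      ag_zero_grad(model$params)
      pred <- model$forward(xb, training = TRUE)
      loss <- op_dice_loss(pred, yb, eps = cfg$loss$epsilon,
                           symmetric = cfg$loss$symmetric_eps)
      if (!is.finite(loss$value)) {
        stop(sprintf("non-finite training loss at epoch %d (batch starting %d)",
                     epoch, start))
      }
      ag_backward(loss)
      adam_step(model$params, opt, lr = cfg$learning_rate)
      losses <- c(losses, loss$value)
    }
    vd <- if (length(val_items)) {
      batch_val_dice(model, val_items, cfg$model$output_threshold)
    } else {
      NA_real_
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %3d | train loss %.4f | val dice %s", epoch,
                      mean(losses),
                      if (is.na(vd)) "--" else sprintf("%.4f", vd)))
    }
    if (!is.na(vd) && vd > best_dice + 1e-6) {
      best_dice <- vd
      best_epoch <- epoch
    }
    if (!is.na(vd) && epoch - best_epoch >= cfg$patience) break
  }

  save_checkpoint(model, cfg$checkpoint, extra = list(window = cfg$window,
                                                      clahe = cfg$clahe))
  structure(list(model = model, log = log, checkpoint = cfg$checkpoint,
                 dataset = dataset, config = cfg),
            class = "train_result")
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint embeds the full [model_config()] plus preprocessing
#' settings, so evaluation never needs the original configuration file.
#'
#' @param model An `msau_model`.
#' @param path Destination `.rds` path.
#' @param extra Named list stored alongside (e.g. window settings).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "msau_model"))
  payload <- list(
    cfg = model$cfg,
    params = lapply(model$params, function(p) p$value),
    states = lapply(model$states, function(s) list(mean = s$mean, var = s$var)),
    extra = extra
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  model <- build_model(payload$cfg, seed = 1L)
  if (!identical(sort(names(model$params)), sort(names(payload$params)))) {
    stop("checkpoint parameters do not match the architecture")
  }
  for (nm in names(payload$params)) {
    model$params[[nm]]$value <- payload$params[[nm]]
  }
  for (nm in names(payload$states)) {
    model$states[[nm]]$mean <- payload$states[[nm]]$mean
    model$states[[nm]]$var <- payload$states[[nm]]$var
  }
  attr(model, "extra") <- payload$extra
  model
}

#' Evaluate a trained model on a dataset split
#'
#' Applies the preprocessing recorded in the checkpoint (or given
#' explicitly), thresholds the predicted probabilities and computes the
#' seven-metric report.
#'
#' @param model An `msau_model`, a `train_result`, or a checkpoint path.
#' @param dataset A `phantom_dataset` (or list of `phantom_pair`).
#' @param split Which split to evaluate (`"test"`, `"val"`, `"train"` or
#'   `"all"`).
#' @param window,clahe Preprocessing overrides; defaults come from the
#'   checkpoint when available.
#' @param label Report label.
#' @return A `metrics_report`.
#' @export
run_evaluation <- function(model, dataset, split = "test", window = NULL,
                           clahe = NULL, label = NULL) {
  if (inherits(model, "train_result")) model <- model$model
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "msau_model"))
  extra <- attr(model, "extra")
  if (is.null(window)) window <- if (!is.null(extra$window)) extra$window else window_spec()
  if (is.null(clahe)) clahe <- isTRUE(extra$clahe)
  pairs <- if (inherits(dataset, "phantom_dataset")) {
    if (split == "all") dataset$pairs else dataset$pairs[dataset$split == split]
  } else {
    dataset
  }
  if (!length(pairs)) stop("no cases in the requested split")
  items <- preprocess_pairs(pairs, window, clahe)
  mask_pairs <- lapply(items, function(it) {
    list(gt = it$y, pred = predict_mask(model, it$x))
  })
  if (is.null(label)) {
    label <- sprintf("MSAU-Net %s (n=%d, %s)", model$cfg$version,
                     model$cfg$n_msa_blocks, model$cfg$attention)
  }
  evaluate_masks(mask_pairs, label = label)
}

#' Ablation grid over version / attention / MSA-block count
#'
#' Trains one model per grid cell on a shared dataset and seed, evaluates
#' all cells on the identical test cases (paired design), and compares the
#' cells per metric with ANOVA + LSD.
#'
#' @param base_cfg A [train_config()] providing everything except the
#'   varied fields.
#' @param versions Character subset of `c("V1", "V2")`.
#' @param attentions Character subset of `c("sSE", "MSSA")`.
#' @param n_msa Integer vector of MSA-block counts.
#' @param verbose Print progress.
#' @return Object of class `ablation_result`: `reports` (one
#'   `metrics_report` per cell), `comparison` (a `model_comparison`),
#'   `failed` (named character vector of cell errors, if any).
#' @export
run_ablation <- function(base_cfg, versions = c("V1", "V2"),
                         attentions = c("sSE", "MSSA"), n_msa = 1:4,
                         verbose = FALSE) {
  stopifnot(inherits(base_cfg, "train_config"))
  dataset <- resolve_dataset(base_cfg$data, derive_seeds(base_cfg$seed, 1L))
  reports <- list()
  failed <- character(0)
  for (v in versions) {
    for (att in attentions) {
      for (nm in n_msa) {
        cell <- sprintf("%s_%s_n%d", v, att, nm)
        if (verbose) message("ablation cell: ", cell)
        res <- tryCatch({
          mc <- base_cfg$model
          mc$version <- v
          mc$attention <- att
          mc$n_msa_blocks <- as.integer(nm)
          cfg <- base_cfg
          cfg$model <- mc
          cfg$data <- dataset
          cfg$checkpoint <- tempfile(fileext = ".rds")
          tr <- run_training(cfg)
          run_evaluation(tr, dataset, split = "test", label = cell)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failed[cell] <- conditionMessage(res)
        } else {
          reports[[cell]] <- res
        }
      }
    }
  }
  comparison <- if (length(reports) >= 2L) compare_reports(reports) else NULL
  structure(list(reports = reports, comparison = comparison, failed = failed,
                 dataset = dataset),
            class = "ablation_result")
}
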