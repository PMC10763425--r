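#' Training configuration
#'
#' Defaults are the full-scale recipe: batch size 16, AdamW with initial
#' learning rate 5e-5, first-moment coefficient 0.9 and decoupled weight
#' decay 1e-4, a step schedule multiplying the learning rate by 0.1 every
#' 5 epochs, and 100 epochs. ("Momentum" is read as AdamW's first-moment
#' coefficient; the second-moment coefficient stays at its conventional
#' 0.999.)
#'
#' @param batch_size mini-batch size (`>= 1`).
#' @param lr0 initial learning rate (`> 0`).
#' @param beta1 first-moment coefficient in `[0,1)`.
#' @param weight_decay decoupled weight-decay coefficient (`>= 0`).
#' @param lr_step epochs between learning-rate drops (`>= 1`).
#' @param lr_gamma multiplicative drop factor in `(0,1]`.
#' @param max_epochs number of training epochs.
#' @param seed seed controlling data order and any remaining randomness.
#' @param loss_name `"cross_entropy"`, `"focal"` or `"modified_focal"`.
#' @param device label only; all computation is CPU.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 16L, lr0 = 5e-5, beta1 = 0.9,
                         weight_decay = 1e-4, lr_step = 5L, lr_gamma = 0.1,
                         max_epochs = 100L, seed = 1L,
                         loss_name = c("modified_focal", "focal",
                                       "cross_entropy"),
                         device = "cpu") {
  loss_name <- match.arg(loss_name)
  cfg <- list(batch_size = as.integer(batch_size), lr0 = lr0, beta1 = beta1,
              weight_decay = weight_decay, lr_step = as.integer(lr_step),
              lr_gamma = lr_gamma, max_epochs = as.integer(max_epochs),
              seed = as.integer(seed), loss_name = loss_name, device = device)
  if (cfg$batch_size < 1L) pn_stop("batch_size must be >= 1",
                                   "pneumonet_config_error")
  if (cfg$lr0 <= 0) pn_stop("lr0 must be positive", "pneumonet_config_error")
  if (cfg$beta1 < 0 || cfg$beta1 >= 1)
    pn_stop("beta1 must lie in [0,1)", "pneumonet_config_error")
  if (cfg$weight_decay < 0)
    pn_stop("weight_decay must be non-negative", "pneumonet_config_error")
  if (cfg$lr_step < 1L) pn_stop("lr_step must be >= 1",
                                "pneumonet_config_error")
  if (cfg$lr_gamma <= 0 || cfg$lr_gamma > 1)
    pn_stop("lr_gamma must lie in (0,1]", "pneumonet_config_error")
  if (cfg$max_epochs < 1L) pn_stop("max_epochs must be >= 1",
                                   "pneumonet_config_error")
  class(cfg) <- "train_config"
  cfg
}

#' Desk-scale training configuration
#'
#' Short CPU recipe for the 64 px phantom presets: learning rate 1e-3
#' (the full-scale 5e-5 is tuned to a far larger model and dataset), the
#' same step-schedule shape, and at most 15 epochs.
#'
#' @param lr0,max_epochs,... see [train_config()].
#' @return a `train_config`.
#' @export
desk_train_config <- function(lr0 = 1e-3, max_epochs = 10L, ...)
  train_config(lr0 = lr0, max_epochs = max_epochs, ...)

#' Learning rate at a given epoch under the step schedule
#'
#' `lr0 * lr_gamma ^ floor(epoch / lr_step)`; with the full-scale defaults
#' this is 5e-5 for epochs 0-4, 5e-6 for epochs 5-9, 5e-7 for 10-14, and
#' so on.
#'
#' @param config a [train_config()].
#' @param epoch non-negative epoch index (0-based).
#' @return the learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr0 * config$lr_gamma^(epoch %/% config$lr_step)
}

softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# resolve a loss name to a per-batch function returning the per-sample loss
# and its derivative w.r.t. the predicted class-1 probability
make_loss <- function(loss_name, lc) {
  switch(loss_name,
    cross_entropy = function(y, p)
      list(l = cross_entropy(y, p, reduction = "none", eps = lc$eps),
           g = cross_entropy_grad(y, p, eps = lc$eps)),
    focal = function(y, p) {
      at <- ifelse(y == 1, lc$alpha, 1 - lc$alpha)
      list(l = focal_loss(y, p, alpha_t = at, gamma = lc$gamma,
                          reduction = "none", eps = lc$eps),
           g = focal_loss_grad(y, p, alpha_t = at, gamma = lc$gamma,
                               eps = lc$eps))
    },
    modified_focal = function(y, p) {
      lcn <- lc
      lcn$reduction <- "none"
      list(l = modified_focal_loss(y, p, lcn),
           g = modified_focal_loss_grad(y, p, lcn))
    },
    pn_stop(paste0("unknown loss: ", loss_name), "pneumonet_config_error"))
}

#' Train a model
#'
#' Mini-batch AdamW optimization with the step learning-rate schedule and
#' the configured loss. Per epoch the mean training loss, the validation
#' accuracy on the full validation set, and the learning rate are
#' recorded. Fully seeded: the same model, data and config reproduce the
#' history exactly.
#'
#' @param model a `pneumonet_model`.
#' @param train_set,val_set non-empty `xray_dataset`s (or
#'   `list(x = array, y = labels)` batches).
#' @param config a [train_config()].
#' @param loss_cfg a [loss_config()] for the focal losses; class counts
#'   default to the training-set label counts.
#' @return `list(model = trained model, history = data.frame(epoch,
#'   train_loss, val_accuracy, lr))`.
#' @export
train_model <- function(model, train_set, val_set,
                        config = desk_train_config(), loss_cfg = NULL) {
  tr <- if (is.list(train_set) && !is.null(train_set$x)) train_set
        else as_batch_array(train_set)
  va <- if (is.list(val_set) && !is.null(val_set$x)) val_set
        else as_batch_array(val_set)
  n <- length(tr$y)
  if (n == 0L || length(va$y) == 0L)
    pn_stop("training and validation sets must be non-empty",
            "pneumonet_data_error")
  if (is.null(loss_cfg))
    loss_cfg <- loss_config(n_normal = max(1L, sum(tr$y == 0)),
                            n_pneumonia = max(1L, sum(tr$y == 1)))
  loss_fn <- make_loss(config$loss_name, loss_cfg)

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_accuracy = numeric(0), lr = numeric(0))
  with_seed(config$seed, {
    state <- adamw_init(model$net)
    t <- 0L
    for (epoch in 0:(config$max_epochs - 1L)) {
      lr <- lr_at_epoch(config, epoch)
      ord <- sample.int(n)
      tot_loss <- 0
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        idx <- ord[i:j]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- tr$y[idx]
        fw <- forward_model(model, xb, training = TRUE)
        model <- fw$model
        pr <- softmax_rows(fw$logits)
        p1 <- pr[, 2L]
        lo <- loss_fn(yb, p1)
        if (!all(is.finite(lo$l)))
          pn_stop(sprintf(
            "non-finite loss in epoch %d, batch starting at sample %d",
            epoch, i), "pneumonet_train_error")
        tot_loss <- tot_loss + sum(lo$l)
        # chain rule through the 2-class softmax: dp1/dz = p1(1-p1) * (±1)
        nb <- length(yb)
        dz1 <- (lo$g / nb) * p1 * (1 - p1)
        glogits <- cbind(-dz1, dz1)
        bw <- backward_unit(model$net, fw$cache, glogits)
        t <- t + 1L
        r <- adamw_step_unit(model$net, bw$grads, state, lr,
                             config$weight_decay, config$beta1, 0.999, 1e-8,
                             1 - config$beta1^t, 1 - 0.999^t)
        model$net <- r$unit
        state <- r$state
        i <- j + 1L
      }
      acc <- mean((apply(predict(model, va$x), 1L, which.max) - 1L) == va$y)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot_loss / n,
                                     val_accuracy = acc, lr = lr))
    }
  })
  list(model = model, history = hist)
}

#' Evaluate a classifier on a labeled dataset
#'
#' Predicts logits, takes the arg-max class per sample, builds the
#' confusion matrix against the true labels (positive class 1 =
#' pneumonia) and returns the full metrics report.
#'
#' @param model an object with a [predict()] method returning an
#'   `N x n_classes` logit (or score) matrix.
#' @param dataset a non-empty `xray_dataset` or `list(x = , y = )` batch.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, dataset) {
  ba <- if (is.list(dataset) && !is.null(dataset$x)) dataset
        else as_batch_array(dataset)
  if (length(ba$y) == 0L)
    pn_stop("dataset must be non-empty", "pneumonet_data_error")
  logits <- predict(model, ba$x)
  y_pred <- apply(logits, 1L, which.max) - 1L
  metrics_report(confusion_matrix(ba$y, y_pred))
}

ablation_variants <- c("resnet_ce", "attention_ce", "attention_focal")

#' Ablation runner
#'
#' Trains three variants on identical seeded data per replicate seed:
#' (a) the residual baseline with cross-entropy, (b) the side-branch
#' attention network with cross-entropy, and (c) the attention network
#' with the class-count-normalized focal loss. Emits one metrics row per
#' variant and seed plus a per-variant mean/sd summary.
#'
#' @param spec a [phantom_spec()] for the per-seed datasets.
#' @param seeds integer vector of replicate seeds.
#' @param train_counts,val_counts per-class split counts (see
#'   [split_dataset()]); defaults fit the desk-scale 270/100 preset.
#' @param net_config attention-network config (desk preset default).
#' @param base_config training config shared by all variants
#'   (`loss_name` is overridden per variant).
#' @param modified_count_mapping count mapping for variant (c).
#' @return `list(results = per-run data.frame, summary = per-variant
#'   data.frame, histories = list)`.
#' @export
run_ablation <- function(spec = phantom_spec(),
                         seeds = 1:5,
                         train_counts = c(pneumonia = 230, normal = 70),
                         val_counts = c(pneumonia = 40, normal = 30),
                         net_config = desk_network_config(),
                         base_config = desk_train_config(),
                         modified_count_mapping = "per_class") {
  rows <- list()
  histories <- list()
  for (sd_i in seeds) {
    spec_i <- spec
    spec_i$seed <- as.integer(sd_i)
    ds <- generate_dataset(spec_i)
    sp <- split_dataset(ds, train_counts, val_counts, seed = sd_i)
    tr <- as_batch_array(sp$train)
    va <- as_batch_array(sp$validation)
    lc <- loss_config(n_normal = sum(tr$y == 0), n_pneumonia = sum(tr$y == 1),
                      count_mapping = modified_count_mapping)
    for (variant in ablation_variants) {
      tc <- base_config
      tc$seed <- as.integer(sd_i)
      tc$loss_name <- switch(variant, resnet_ce = "cross_entropy",
                             attention_ce = "cross_entropy",
                             attention_focal = "modified_focal")
      ncfg <- net_config
      ncfg$seed <- as.integer(sd_i)
      mdl <- if (variant == "resnet_ce") {
        rc <- ncfg
        rc$n_blocks <- 4L
        build_resnet_baseline(rc)
      } else build_attention_net(ncfg)
      fit <- train_model(mdl, tr, va, tc, loss_cfg = lc)
      rep <- evaluate_model(fit$model, va)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, seed = sd_i, accuracy = rep$accuracy,
        precision = rep$precision, recall = rep$recall,
        specificity = rep$specificity, f1 = rep$f1,
        tp = rep$cm$tp, fp = rep$cm$fp, tn = rep$cm$tn, fn = rep$cm$fn,
        stringsAsFactors = FALSE)
      histories[[paste(variant, sd_i, sep = "_")]] <- fit$history
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$variant), function(d) {
    data.frame(variant = d$variant[1L],
               accuracy_mean = mean(d$accuracy), accuracy_sd = sd(d$accuracy),
               recall_mean = mean(d$recall), recall_sd = sd(d$recall),
               specificity_mean = mean(d$specificity),
               specificity_sd = sd(d$specificity),
               f1_mean = mean(d$f1), f1_sd = sd(d$f1),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[match(ablation_variants, summ$variant), ]
  rownames(summ) <- NULL
  list(results = results, summary = summ, histories = histories)
}
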