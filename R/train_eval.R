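#' Build the constant-current drive matrix for a dataset split
#'
#' @param split A list with `samples` (pixel matrices) and `labels`.
#' @param cfg An [encoder_config()].
#' @return An `n_pixels x n_samples` matrix of input currents.
#' @export
dataset_drive_matrix <- function(split, cfg) {
  vapply(split$samples,
         function(m) cfg$current_scale * as.numeric(m) / cfg$pixel_max,
         numeric(length(split$samples[[1]])))
}

# Rate matrix (Hz) for Poisson encoding of a split.
dataset_rate_matrix <- function(split, cfg) {
  vapply(split$samples,
         function(m) cfg$poisson_max_rate * as.numeric(m) / cfg$pixel_max,
         numeric(length(split$samples[[1]])))
}

#' Train the network on a dataset, unsupervised
#'
#' Presents every sample once per epoch with learning enabled, in an order
#' reshuffled each epoch from `shuffle_seed`. Neuron states carry over
#' between samples (no reset, no wait time). Labels are never used: the
#' plasticity rule alone shapes the weights.
#'
#' @param net A [network_init()] network.
#' @param split A dataset split (list with `samples`, `labels`).
#' @param epochs Number of passes over the data (0 leaves the network
#'   unchanged).
#' @param encoder An [encoder_config()]; its `mode` selects constant-current
#'   or Poisson drive.
#' @param shuffle_seed Seed for the per-epoch shuffles (default: the
#'   network's seed).
#' @param verbose Print a per-epoch log line (mean weight, output spikes).
#'
#' @return The trained network, with an `epoch_log` data.frame attached as
#'   attribute `"epoch_log"`.
#' @export
train_network <- function(net, split, epochs = 1,
                          encoder = encoder_config(),
                          shuffle_seed = net$config$seed, verbose = FALSE) {
  n <- length(split$samples)
  if (n == 0) stop("empty dataset", call. = FALSE)
  steps <- round(net$config$present_ms / net$config$dt)
  log <- data.frame(epoch = integer(0), mean_weight = numeric(0),
                    output_spikes = integer(0))
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      set.seed(shuffle_seed + ep - 1L)
      ord <- sample.int(n)
      if (encoder$mode == "poisson") {
        rates <- dataset_rate_matrix(split, encoder)[, ord, drop = FALSE]
        res <- run_pass(net, rates, steps, learn = TRUE, mode = "poisson")
      } else {
        drive <- dataset_drive_matrix(split, encoder)[, ord, drop = FALSE]
        res <- run_pass(net, drive, steps, learn = TRUE, mode = "constant")
      }
      net <- res$net
      log <- rbind(log, data.frame(epoch = ep, mean_weight = mean(net$W),
                                   output_spikes = sum(res$counts)))
      if (verbose) {
        message(sprintf("epoch %d: mean weight %.4f, %d output spikes",
                        ep, mean(net$W), sum(res$counts)))
      }
    }
  }
  attr(net, "epoch_log") <- log
  net
}

# Run a split with learning off; returns counts (n_samples x n_out).
inference_counts <- function(net, split, encoder) {
  steps <- round(net$config$present_ms / net$config$dt)
  if (encoder$mode == "poisson") {
    rates <- dataset_rate_matrix(split, encoder)
    res <- run_pass(net, rates, steps, learn = FALSE, mode = "poisson")
  } else {
    drive <- dataset_drive_matrix(split, encoder)
    res <- run_pass(net, drive, steps, learn = FALSE, mode = "constant")
  }
  res$counts
}

#' Assign a class label to every output neuron
#'
#' With weights fixed, the (training) split is presented again and spike
#' counts are accumulated per (neuron, true class). Each neuron is labeled
#' with its argmax class; ties break toward the lowest class id. Neurons
#' that never spiked are flagged `dead` and labeled class 1 by the
#' tie-break.
#'
#' @param net A trained network (weights are not modified).
#' @param split The labeling split.
#' @param encoder An [encoder_config()].
#' @param n_classes Number of classes (default: max label in the split).
#'
#' @return An object of class `"label_map"`: `neuron_to_class` (integer
#'   vector), `class_spike_totals` (neurons x classes matrix), `dead`
#'   (logical vector).
#' @export
assign_labels <- function(net, split, encoder = encoder_config(),
                          n_classes = max(split$labels)) {
  counts <- inference_counts(net, split, encoder)
  totals <- matrix(0, nrow = net$config$n_out, ncol = n_classes)
  for (cl in seq_len(n_classes)) {
    sel <- split$labels == cl
    if (any(sel)) totals[, cl] <- colSums(counts[sel, , drop = FALSE])
  }
  labels <- apply(totals, 1, which.max)  # ties: lowest class id
  dead <- rowSums(totals) == 0
  labels[dead] <- 1L
  structure(list(neuron_to_class = as.integer(labels),
                 class_spike_totals = totals, dead = dead),
            class = "label_map")
}

#' Predict the class of a presentation from per-neuron spike counts
#'
#' The score of a class is the cumulative spike count of all neurons
#' carrying that label; the argmax wins, ties break toward the lowest class
#' id. An all-zero count vector predicts class 1 and is flagged
#' low-confidence.
#'
#' @param counts Per-neuron spike counts: a vector, or an
#'   `n_samples x n_out` matrix for many presentations at once.
#' @param labels A [assign_labels()] label map.
#'
#' @return Integer class id(s), with attribute `"low_confidence"` (logical).
#' @export
predict_class <- function(counts, labels) {
  if (is.matrix(counts)) {
    n_classes <- ncol(labels$class_spike_totals)
    member <- outer(labels$neuron_to_class, seq_len(n_classes), "==") * 1
    scores <- counts %*% member       # n_samples x n_classes
    pred <- max.col(scores, ties.method = "first")
    structure(as.integer(pred), low_confidence = rowSums(counts) == 0)
  } else {
    scores <- tapply(counts, labels$neuron_to_class, sum)
    full <- rep(0, ncol(labels$class_spike_totals))
    full[as.integer(names(scores))] <- scores
    structure(which.max(full), low_confidence = sum(counts) == 0)
  }
}

#' Evaluate a trained, labeled network on a test split
#'
#' Runs every test sample with learning disabled, predicts with
#' [predict_class()], and tallies accuracy, the confusion matrix (rows =
#' true class), per-neuron spike totals and the weight mid-band fraction.
#'
#' @param net A trained network.
#' @param split The evaluation split.
#' @param labels A [assign_labels()] label map.
#' @param encoder An [encoder_config()].
#'
#' @return An object of class `"evaluation_report"`.
#' @export
evaluate_network <- function(net, split, labels,
                             encoder = encoder_config()) {
  counts <- inference_counts(net, split, encoder)
  pred <- predict_class(counts, labels)
  n_classes <- ncol(labels$class_spike_totals)
  confusion <- table(factor(split$labels, levels = seq_len(n_classes)),
                     factor(pred, levels = seq_len(n_classes)))
  structure(
    list(accuracy = mean(pred == split$labels),
         confusion = unclass(confusion),
         per_neuron_spikes = colSums(counts),
         midband_fraction = weight_bimodality(net$W),
         n_samples = length(split$labels)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy: %.1f%% on %d samples\n",
              100 * x$accuracy, x$n_samples))
  cat(sprintf("weight mid-band (0.2, 0.8) fraction: %.3f\n",
              x$midband_fraction))
  cat("confusion (rows = true class):\n")
  print(x$confusion)
  invisible(x)
}

#' Fraction of weights in the open mid-band (0.2, 0.8)
#'
#' A bimodal weight distribution — most weights saturated near 0 or near
#' `w_max` — has a small mid-band fraction; uniform random weights score
#' 0.6. Training is expected to drive this fraction down from its initial
#' value.
#'
#' @param W Weight matrix with entries in `[0, 1]`.
#' @return Fraction of entries strictly inside `(0.2, 0.8)`.
#' @export
weight_bimodality <- function(W) {
  mean(W > 0.2 & W < 0.8)
}

#' Receptive-field purity against class prototypes
#'
#' For each non-dead output neuron, checks whether its weight vector has
#' maximal cosine similarity with the prototype of its assigned class.
#'
#' @param net A trained network.
#' @param labels A [assign_labels()] label map.
#' @param prototypes List of class prototype matrices.
#'
#' @return A list with `purity` (fraction of non-dead neurons whose best
#'   matching prototype is their assigned class) and `best_class` per
#'   neuron.
#' @export
receptive_field_purity <- function(net, labels, prototypes) {
  P <- vapply(prototypes, as.numeric, numeric(length(prototypes[[1]])))
  P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  Wn <- sweep(net$W, 2, sqrt(colSums(net$W^2)) + 1e-12, "/")
  sim <- t(Wn) %*% P                   # n_out x n_classes
  best <- max.col(sim, ties.method = "first")
  alive <- !labels$dead
  list(purity = mean(best[alive] == labels$neuron_to_class[alive]),
       best_class = best)
}

#' End-to-end unsupervised train / label / evaluate run
#'
#' Convenience wrapper: initializes a network, trains it on the training
#' split, labels neurons on the same split with weights fixed, and
#' evaluates on the test split.
#'
#' @param dataset A [sample_dataset()] result (or compatible list with
#'   `train`, `test`, `prototypes`).
#' @param n_out Number of output neurons.
#' @param seed Seed for weight initialization and shuffling.
#' @param epochs Training epochs.
#' @param lr VDSP learning rate.
#' @param rule `"vdsp"` or `"stdp"`.
#' @param encoder An [encoder_config()].
#' @param ... Further arguments passed to [network_config()].
#'
#' @return A list with `net`, `labels`, `report`, `purity` and
#'   `initial_midband` (mid-band fraction of the untrained weights).
#' @export
run_experiment <- function(dataset, n_out = 30, seed = 1, epochs = 1,
                           lr = 0.05, rule = "vdsp",
                           encoder = encoder_config(), ...) {
  n_in <- length(dataset$train$samples[[1]])
  cfg <- network_config(n_in = n_in, n_out = n_out, rule = rule, seed = seed,
                        plasticity = vdsp_params(lr = lr), ...)
  net <- network_init(cfg)
  initial_midband <- weight_bimodality(net$W)
  net <- train_network(net, dataset$train, epochs = epochs,
                       encoder = encoder, shuffle_seed = seed)
  labels <- assign_labels(net, dataset$train, encoder = encoder)
  report <- evaluate_network(net, dataset$test, labels, encoder = encoder)
  purity <- receptive_field_purity(net, labels, dataset$prototypes)
  list(net = net, labels = labels, report = report, purity = purity,
       initial_midband = initial_midband)
}

#' Input-frequency robustness experiment
#'
#' Compares how a plasticity rule tolerates global scaling of the input
#' currents, with fixed (non-retuned) rule parameters. For each scale the
#' full-scale pixel current is `base_current * scale`, output-layer
#' adaptation is disabled, and the presentation duration is set dynamically
#' so the brightest pixel's neuron emits at most ten spikes per image
#' (10 x its closed-form inter-spike interval, rounded up to a multiple of
#' `dt`). The network is trained for one epoch, labeled on the training
#' split and evaluated on the test split.
#'
#' @param dataset A [sample_dataset()] result.
#' @param scales Positive multipliers applied to the input currents.
#' @param rule `"vdsp"` or `"stdp"`.
#' @param seeds Integer seeds (one run per seed per scale).
#' @param n_out Output neurons (default 10).
#' @param base_current Full-scale pixel current at scale 1. The default of 2
#'   keeps the brightest pixel supra-threshold across all scales >= 0.5
#'   with the standard input bias of 0.5.
#' @param lr VDSP learning rate.
#' @param stdp An [stdp_params()] used when `rule = "stdp"`; the default
#'   enables the target-trace offset (`x_tar = 0.2`) without which
#'   competitive unsupervised STDP cannot form receptive fields.
#'
#' @return A data.frame with columns `scale`, `seed`, `accuracy`,
#'   `duration_ms` and `rule`. Scales at which no input neuron can fire are
#'   flagged with `degenerate = TRUE` and `NA` accuracy.
#' @export
frequency_robustness <- function(dataset, scales = c(0.5, 1, 2, 4),
                                 rule = "vdsp", seeds = 1:5, n_out = 10,
                                 base_current = 2, lr = 0.05,
                                 stdp = stdp_params(x_tar = 0.2)) {
  n_in <- length(dataset$train$samples[[1]])
  in_params <- lif_params(bias = 0.5)
  out_params <- alif_params(inc_n = 0)   # adaptation disabled
  dt <- 5
  out <- expand.grid(scale = scales, seed = seeds)
  out$accuracy <- NA_real_
  out$duration_ms <- NA_real_
  out$degenerate <- FALSE
  for (r in seq_len(nrow(out))) {
    sc <- out$scale[r]
    isi <- closed_form_isi(in_params, base_current * sc)
    if (!is.finite(isi)) {
      out$degenerate[r] <- TRUE
      next
    }
    duration <- ceiling(10 * isi / dt) * dt
    out$duration_ms[r] <- duration
    enc <- encoder_config(current_scale = base_current * sc)
    cfg <- network_config(n_in = n_in, n_out = n_out, dt = dt,
                          present_ms = duration, rule = rule,
                          seed = out$seed[r], in_params = in_params,
                          out_params = out_params,
                          plasticity = vdsp_params(lr = lr), stdp = stdp)
    net <- network_init(cfg)
    net <- train_network(net, dataset$train, epochs = 1, encoder = enc,
                         shuffle_seed = out$seed[r])
    labels <- assign_labels(net, dataset$train, encoder = enc)
    rep <- evaluate_network(net, dataset$test, labels, encoder = enc)
    out$accuracy[r] <- rep$accuracy
  }
  out$rule <- rule
  out
}
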