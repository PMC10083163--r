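#' Configuration of the patch-classifier backbone
#'
#' Two variants of a densely connected convolutional classifier are
#' supported. `densenet161` is the full configuration: a 7x7 stride-2 stem
#' convolution, 3x3 stride-2 max pooling, four dense blocks of 6/12/36/24
#' bottlenecked layers with growth rate 48 and compression 0.5 in the
#' transition layers, batch normalization and ReLU before every dense-block
#' convolution and transition layer, a final batch normalization before the
#' classifier, and a softmax-normalized fully connected head. On a 64x64
#' patch its feature maps shrink 32, 16, 8, 4, 2 through the stages.
#' `reduced` keeps the identical topology at desk scale (3x3 stem, three
#' dense blocks, small growth) so every training-regime operation can be
#' exercised quickly; all regime logic is variant-agnostic.
#'
#' @param variant `"densenet161"` or `"reduced"`.
#' @param input_side patch side in pixels the model will consume.
#' @param n_classes number of output classes (>= 2).
#' @param block_layout per-block counts of dense layers; defaults to
#'   `c(6, 12, 36, 24)` for the full variant and `c(2, 2, 2)` for reduced.
#' @param growth channels added per dense layer (48 full / 10 reduced).
#' @param init_channels stem convolution output channels (96 full /
#'   16 reduced).
#' @param bn_size bottleneck multiplier (1x1 conv emits `bn_size * growth`).
#' @param compression transition-layer channel compression factor.
#' @param seed RNG seed for initialization.
#' @return a `backbone_config`.
#' @export
backbone_config <- function(variant = c("reduced", "densenet161"),
                            input_side = 64L, n_classes = 4L,
                            block_layout = NULL, growth = NULL,
                            init_channels = NULL, bn_size = 4L,
                            compression = 0.5, seed = 1L) {
  variant <- match.arg(variant)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (variant == "densenet161") {
    block_layout <- block_layout %||% c(6L, 12L, 36L, 24L)
    growth <- growth %||% 48L
    init_channels <- init_channels %||% 96L
    stem_kernel <- 7L
  } else {
    block_layout <- block_layout %||% c(2L, 2L, 2L)
    growth <- growth %||% 10L
    init_channels <- init_channels %||% 16L
    stem_kernel <- 3L
  }
  if (any(block_layout < 1L)) stop("block_layout must be positive")
  structure(list(variant = variant, input_side = as.integer(input_side),
                 n_classes = as.integer(n_classes),
                 block_layout = as.integer(block_layout),
                 growth = as.integer(growth),
                 init_channels = as.integer(init_channels),
                 bn_size = as.integer(bn_size), compression = compression,
                 stem_kernel = stem_kernel, seed = as.integer(seed)),
            class = "backbone_config")
}

#' Build the patch classifier
#'
#' Convolutional weights receive Kaiming (He) initialization; the fully
#' connected head is uniform-initialized. The terminal softmax turns the
#' head's scores into a class probability vector (see [predict_proba()]).
#'
#' @param config a [backbone_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an `oct_model`: list with the module tree (`net`), `config`,
#'   `n_classes`, `classes` (names assigned at training time), `variant`,
#'   `provenance` (`scratch` until a pretraining regime tags it) and
#'   `stage_sizes`, the spatial side of the feature map after the stem
#'   convolution, the stem pooling and each dense block.
#' @export
build_backbone <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "backbone_config"))
  side <- config$input_side
  with_seed(seed, {
    modules <- list(
      nn_conv(1L, config$init_channels, config$stem_kernel, stride = 2L,
              pad = (config$stem_kernel - 1L) %/% 2L),
      nn_bn(config$init_channels), nn_relu(), nn_maxpool(3L, 2L, 1L)
    )
    stage_sizes <- integer(0)
    s <- (side + 2L * ((config$stem_kernel - 1L) %/% 2L) - config$stem_kernel) %/% 2L + 1L
    stage_sizes <- c(stage_sizes, s)
    s <- (s + 2L - 3L) %/% 2L + 1L
    stage_sizes <- c(stage_sizes, s)
    ch <- config$init_channels
    nb <- length(config$block_layout)
    for (b in seq_len(nb)) {
      blk <- nn_dense_block(ch, config$block_layout[b], config$growth, config$bn_size)
      modules[[length(modules) + 1L]] <- blk
      ch <- blk$out_ch
      if (b < nb) {
        out_ch <- as.integer(max(1L, floor(ch * config$compression)))
        modules[[length(modules) + 1L]] <- nn_transition(ch, out_ch)
        ch <- out_ch
        s <- s %/% 2L
        stage_sizes <- c(stage_sizes, s)
      }
    }
    modules <- c(modules, list(nn_bn(ch), nn_relu(), nn_gap(),
                               nn_linear(ch, config$n_classes)))
    structure(list(net = nn_seq(modules), config = config,
                   n_classes = config$n_classes,
                   classes = oct_classes()[seq_len(min(4L, config$n_classes))],
                   variant = config$variant, provenance = "scratch",
                   feature_channels = ch, stage_sizes = stage_sizes),
              class = "oct_model")
  })
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf("oct_model (%s): %d classes, %d feature channels, provenance %s\n",
              x$variant, x$n_classes, x$feature_channels, x$provenance))
  invisible(x)
}

#' Replace the classifier head
#'
#' Swaps the terminal fully connected layer for a freshly uniform-initialized
#' one with `n_classes` outputs, preserving every other parameter (and the
#' batch-norm running statistics) bit for bit. This is the knowledge-transfer
#' primitive shared by the generalist and uncertainty regimes.
#'
#' @param model an `oct_model`.
#' @param n_classes output classes of the new head (>= 2).
#' @param seed RNG seed for the new head.
#' @param classes optional class names for the new head.
#' @return the model with a new head.
#' @export
replace_head <- function(model, n_classes, seed = 1L, classes = NULL) {
  stopifnot(inherits(model, "oct_model"))
  if (n_classes < 2L) stop("n_classes must be >= 2")
  k <- length(model$net$children)
  head <- model$net$children[[k]]
  stopifnot(head$kind == "linear")
  model$net$children[[k]] <- with_seed(seed, nn_linear(head$in_f, n_classes))
  model$n_classes <- as.integer(n_classes)
  model$classes <- classes %||%
    (if (n_classes == 4L) oct_classes() else paste0("class", seq_len(n_classes)))
  model
}

# All parameters except the terminal linear head, flattened (used by the
# head-replacement contract tests and checkpoint checksums).
body_params <- function(model) {
  k <- length(model$net$children)
  unlist(lapply(model$net$children[-k], nn_flatten), recursive = FALSE)
}

#' Class probabilities for a batch of patches
#'
#' @param model an `oct_model`.
#' @param patches array `side x side x n` (or one `side x side` matrix).
#' @param batch_size forward-pass chunk size (memory bound).
#' @return `n x n_classes` matrix of softmax probabilities, columns named by
#'   `model$classes`.
#' @export
predict_proba <- function(model, patches, batch_size = 256L) {
  if (is.matrix(patches)) patches <- array(patches, dim = c(dim(patches), 1L))
  n <- dim(patches)[3]
  out <- matrix(0, n, model$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    t0 <- as_nn_tensor(patches[, , idx, drop = FALSE])
    logits <- nn_forward(model$net, t0, training = FALSE)$y
    out[idx, ] <- t(softmax_cols(logits))
  }
  colnames(out) <- model$classes
  out
}

#' Hard class labels for a batch of patches
#'
#' Argmax of [predict_proba()] with ties broken by the lowest class index.
#'
#' @inheritParams predict_proba
#' @return character vector of predicted class names.
#' @export
predict_label <- function(model, patches, batch_size = 256L) {
  probs <- predict_proba(model, patches, batch_size)
  model$classes[max.col(probs, ties.method = "first")]
}

#' Save / load a model checkpoint
#'
#' The weight file is R's native serialization; a JSON sidecar records the
#' configuration and provenance so a checkpoint is self-describing.
#'
#' @param model an `oct_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(variant = model$variant, n_classes = model$n_classes,
               classes = model$classes, provenance = model$provenance,
               input_side = model$config$input_side,
               block_layout = model$config$block_layout,
               growth = model$config$growth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
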