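#' Configuration of the group-supervised dose-prediction network
#'
#' An 18-block volumetric encoder-decoder. Blocks 1-12 form the encoding
#' group, blocks 13-18 the decoding group. Each ConvBlock is a 3x3x3
#' convolution, instance normalization (batch size is 1, so batch statistics
#' would be degenerate) and ReLU; the blocks after `downsample_after`
#' positions open a new encoder stage with a stride-2 convolution and
#' doubled channels, and the decoder mirrors the stages with trilinear
#' 2x upsampling before blocks 13, 15 and 17. Besides its output path to
#' the next block, every block feeds a side path -- a 1x1x1 convolution
#' restored to input resolution by trilinear upsampling -- into its group's
#' feature pyramid; each group fuses its pyramid by a learned linear
#' combination into a group prediction with its own loss, and a 1x1x1 head
#' on block 18 gives the final prediction. Optimized with Adam at learning
#' rate 6e-4 and batch size 1 under an L1 + MSE objective per group.
#'
#' @param in_channels Input channels: CT + projected volume + one per ROI
#'   mask (default 9 for the seven-ROI thoracic set).
#' @param base_channels Channels of the first encoder stage (16 at full
#'   scale; 4 for the desk-scale profile that all tests use).
#' @param downsample_after Encoder block indices after which resolution
#'   halves (default 3, 6, 9).
#' @param loss_weights Named weights `c(encoder, decoder, final)`.
#' @param lr Adam learning rate (default 6e-4).
#' @param steps Training steps (batch size 1: one sample per step).
#' @param seed Integer seed fixing weight initialization and sample order.
#' @param roi_order ROI mask channel order.
#' @return A `wingsnet_config` list.
#' @export
wingsnet_config <- function(in_channels = 9L, base_channels = 16L,
                            downsample_after = c(3L, 6L, 9L),
                            loss_weights = c(encoder = 1, decoder = 1, final = 1),
                            lr = 6e-4, steps = 200L, seed = 1L,
                            roi_order = c("PTV", "left_lung", "right_lung",
                                          "total_lung", "heart", "spinal_cord",
                                          "body")) {
  stopifnot(in_channels >= 2, base_channels >= 1, length(loss_weights) == 3)
  structure(list(n_blocks = 18L, encoder_blocks = 1:12, decoder_blocks = 13:18,
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 downsample_after = as.integer(downsample_after),
                 upsample_before = c(13L, 15L, 17L),
                 out_channels = 1L, side_channels = 1L,
                 loss_weights = loss_weights, lr = lr,
                 batch_size = 1L, steps = as.integer(steps),
                 seed = as.integer(seed), roi_order = roi_order),
            class = "wingsnet_config")
}

# Per-block channel/stride/upsample schedule and per-stage shapes.
wingsnet_plan <- function(config, shape0) {
  c0 <- config$base_channels
  stage_of_enc <- cumsum(seq_len(12) %in% (config$downsample_after + 1L))
  enc_ch <- c0 * 2^stage_of_enc
  dec_stage <- c(2, 2, 1, 1, 0, 0)
  dec_ch <- c0 * 2^dec_stage
  ch <- c(enc_ch, dec_ch)
  in_ch <- c(config$in_channels, ch[-18])
  stride <- rep(1L, 18); stride[config$downsample_after + 1L] <- 2L
  shapes <- vector("list", 18)
  cur <- shape0
  stage_shapes <- list(shape0)
  for (t in 1:12) {
    if (stride[t] == 2L) {
      cur <- (cur - 1L) %/% 2L + 1L
      stage_shapes[[length(stage_shapes) + 1L]] <- cur
    }
    shapes[[t]] <- cur
  }
  up_to <- vector("list", 18)
  stage_idx <- length(stage_shapes)
  for (t in 13:18) {
    if (t %in% config$upsample_before) {
      stage_idx <- stage_idx - 1L
      cur <- stage_shapes[[stage_idx]]
      up_to[[t]] <- cur
    }
    shapes[[t]] <- cur
  }
  list(in_ch = in_ch, out_ch = ch, stride = stride, shapes = shapes,
       up_to = up_to, shape0 = shape0)
}

#' Build a WingsNet model
#'
#' Initializes all parameters (He-normal convolution weights, unit-gain
#' instance norms, uniform pyramid-fusion weights) deterministically from
#' the config seed. The model is an explicit parameter list plus config;
#' the forward/backward passes are hand-written (no GPU framework in this
#' stack), which is adequate for the desk-scale volumes the trainer targets.
#'
#' @param config A [wingsnet_config()].
#' @param input_dim Cubic spatial dimension the model will operate at.
#' @return A `wingsnet_model`: list with `params`, `config`, `input_dim`.
#' @export
build_wingsnet <- function(config = wingsnet_config(), input_dim = 24L) {
  shape0 <- rep(as.integer(input_dim), 3)
  pl <- wingsnet_plan(config, shape0)
  if (any(unlist(pl$shapes) < 1)) stop("input_dim too small for the downsampling schedule")
  params <- list()
  with_seed(config$seed, {
    for (t in 1:18) {
      fan_in <- 27 * pl$in_ch[t]
      params[[sprintf("b%02d_W", t)]] <-
        matrix(stats::rnorm(fan_in * pl$out_ch[t], 0, sqrt(2 / fan_in)),
               fan_in, pl$out_ch[t])
      params[[sprintf("b%02d_b", t)]] <- numeric(pl$out_ch[t])
      params[[sprintf("b%02d_gamma", t)]] <- rep(1, pl$out_ch[t])
      params[[sprintf("b%02d_beta", t)]] <- numeric(pl$out_ch[t])
      params[[sprintf("s%02d_W", t)]] <-
        matrix(stats::rnorm(pl$out_ch[t], 0, sqrt(2 / pl$out_ch[t])),
               pl$out_ch[t], 1)
      params[[sprintf("s%02d_b", t)]] <- numeric(1)
    }
    params$fuse_enc_W <- matrix(1 / 12, 12, 1)
    params$fuse_enc_b <- numeric(1)
    params$fuse_dec_W <- matrix(1 / 6, 6, 1)
    params$fuse_dec_b <- numeric(1)
    params$final_W <- matrix(stats::rnorm(pl$out_ch[18], 0,
                                          sqrt(2 / pl$out_ch[18])),
                             pl$out_ch[18], 1)
    params$final_b <- numeric(1)
  })
  structure(list(params = params, config = config,
                 input_dim = as.integer(input_dim), plan = pl),
            class = "wingsnet_model")
}

#' Total trainable parameter count
#'
#' A pure function of the configuration (and input dim, which fixes
#' nothing but validates the schedule).
#'
#' @param config A [wingsnet_config()].
#' @param input_dim Cubic input dimension.
#' @return Integer parameter count.
#' @export
wingsnet_param_count <- function(config = wingsnet_config(), input_dim = 24L) {
  m <- build_wingsnet(config, input_dim)
  sum(vapply(m$params, length, integer(1)))
}

wingsnet_forward <- function(model, x) {
  pl <- model$plan; p <- model$params
  caches <- vector("list", 18)
  sides <- vector("list", 18)
  cur <- x
  cur_shape <- pl$shape0
  for (t in 1:18) {
    cc <- list()
    if (!is.null(pl$up_to[[t]])) {
      up <- upsample_forward(cur, cur_shape, pl$up_to[[t]])
      cc$up <- up$cache; cc$up_from <- cur_shape
      cur <- up$y; cur_shape <- pl$up_to[[t]]
    }
    cv <- conv3_forward(cur, cur_shape, p[[sprintf("b%02d_W", t)]],
                        p[[sprintf("b%02d_b", t)]], pl$stride[t])
    cc$conv <- cv$cache
    inn <- instnorm_forward(cv$y, p[[sprintf("b%02d_gamma", t)]],
                            p[[sprintf("b%02d_beta", t)]])
    cc$inorm <- inn$cache
    rl <- relu_forward(inn$y)
    cc$relu <- rl$cache
    cur <- rl$y; cur_shape <- cv$shape
    sc <- conv1_forward(cur, p[[sprintf("s%02d_W", t)]],
                        p[[sprintf("s%02d_b", t)]])
    cc$side_conv <- sc$cache
    su <- upsample_forward(sc$y, cur_shape, pl$shape0)
    cc$side_up <- su$cache
    sides[[t]] <- su$y
    cc$shape <- cur_shape
    caches[[t]] <- cc
  }
  pyr_enc <- do.call(cbind, sides[1:12])
  pyr_dec <- do.call(cbind, sides[13:18])
  fe <- conv1_forward(pyr_enc, p$fuse_enc_W, p$fuse_enc_b)
  fd <- conv1_forward(pyr_dec, p$fuse_dec_W, p$fuse_dec_b)
  fin <- conv1_forward(cur, p$final_W, p$final_b)
  list(final = fin$y[, 1], enc_pred = fe$y[, 1], dec_pred = fd$y[, 1],
       sides = sides,
       caches = list(blocks = caches, fuse_enc = fe$cache, fuse_dec = fd$cache,
                     final = fin$cache))
}

#' Group-supervised L1 + MSE objective
#'
#' `loss = sum_g w_g * [L1(pred_g, ref) + MSE(pred_g, ref)] +
#' w_final * [L1(final, ref) + MSE(final, ref)]`, over normalized dose.
#' Non-negative, and zero iff every prediction equals the reference.
#'
#' @param group_preds List of group predictions (numeric arrays/vectors),
#'   e.g. encoder and decoder pyramid fusions.
#' @param final_pred Final-head prediction.
#' @param reference Reference (normalized) dose, same shape.
#' @param weights Numeric weights, one per group plus one final weight
#'   (defaults to all 1).
#' @return List with `loss` and per-term `components`.
#' @export
group_loss <- function(group_preds, final_pred, reference,
                       weights = rep(1, length(group_preds) + 1L)) {
  stopifnot(length(weights) == length(group_preds) + 1L)
  ref <- as.numeric(reference)
  comps <- numeric(0)
  total <- 0
  for (i in seq_along(group_preds)) {
    p <- as.numeric(group_preds[[i]])
    if (length(p) != length(ref)) stop("group prediction/reference shape mismatch")
    l <- l1_mse_loss(p, ref)$loss
    comps <- c(comps, l)
    total <- total + weights[i] * l
  }
  fp <- as.numeric(final_pred)
  if (length(fp) != length(ref)) stop("final prediction/reference shape mismatch")
  lf <- l1_mse_loss(fp, ref)$loss
  total <- total + weights[length(weights)] * lf
  list(loss = total, components = c(comps, final = lf))
}

wingsnet_backward <- function(model, fwd, ref, weights) {
  pl <- model$plan; p <- model$params
  grads <- list()
  acc <- function(nm, g) grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  ge <- l1_mse_loss(fwd$enc_pred, ref)$grad * weights[1]
  gd <- l1_mse_loss(fwd$dec_pred, ref)$grad * weights[2]
  gf <- l1_mse_loss(fwd$final, ref)$grad * weights[3]
  be <- conv1_backward(matrix(ge, ncol = 1), fwd$caches$fuse_enc)
  bd <- conv1_backward(matrix(gd, ncol = 1), fwd$caches$fuse_dec)
  bf <- conv1_backward(matrix(gf, ncol = 1), fwd$caches$final)
  acc("fuse_enc_W", be$dW); acc("fuse_enc_b", be$db)
  acc("fuse_dec_W", bd$dW); acc("fuse_dec_b", bd$db)
  acc("final_W", bf$dW); acc("final_b", bf$db)
  dside <- vector("list", 18)
  for (m in 1:12) dside[[m]] <- be$dx[, m]
  for (m in 1:6) dside[[12 + m]] <- bd$dx[, m]
  dmain <- bf$dx  # gradient flowing into block 18's output
  for (t in 18:1) {
    cc <- fwd$caches$blocks[[t]]
    ds <- upsample_backward(matrix(dside[[t]], ncol = 1), cc$side_up)
    sb <- conv1_backward(ds, cc$side_conv)
    acc(sprintf("s%02d_W", t), sb$dW); acc(sprintf("s%02d_b", t), sb$db)
    dy <- sb$dx + (if (is.null(dmain)) 0 else dmain)
    dy <- relu_backward(dy, cc$relu)
    ib <- instnorm_backward(dy, cc$inorm)
    acc(sprintf("b%02d_gamma", t), ib$dgamma)
    acc(sprintf("b%02d_beta", t), ib$dbeta)
    cb <- conv3_backward(ib$dx, cc$conv)
    acc(sprintf("b%02d_W", t), cb$dW); acc(sprintf("b%02d_b", t), cb$db)
    dprev <- cb$dx
    if (!is.null(cc$up)) dprev <- upsample_backward(dprev, cc$up)
    dmain <- if (t > 1) dprev else NULL
  }
  grads
}

# Stack the normalized sample channels into the nvox x C network input.
sample_input_matrix <- function(sample, config) {
  nz <- normalize_for_model(sample)
  chans <- c(list(nz$ct, nz$projected),
             lapply(config$roi_order, function(r) {
               m <- nz$masks[[r]]
               if (is.null(m)) stop("sample is missing ROI mask '", r, "'")
               m
             }))
  x <- do.call(cbind, lapply(chans, as.numeric))
  if (ncol(x) != config$in_channels)
    stop("sample yields ", ncol(x), " channels but config expects ",
         config$in_channels)
  list(x = x, ref = as.numeric(nz$dose))
}

#' Train a WingsNet on model samples
#'
#' Desk-scale CPU trainer: Adam (lr from the config, default 6e-4), batch
#' size 1, one sample per step cycling through the dataset, group-supervised
#' L1 + MSE objective. Fully reproducible for a fixed config seed on one
#' machine.
#'
#' @param samples Non-empty list of [model_sample()]s sharing one cubic dim.
#' @param config A [wingsnet_config()].
#' @param log_csv Optional path for a per-step loss log
#'   (step, loss, encoder/decoder/final components).
#' @return A `wingsnet_fit`: `model` (trained), `history` (data frame).
#' @export
train_wingsnet <- function(samples, config = wingsnet_config(), log_csv = NULL) {
  if (!length(samples)) stop("empty dataset: need at least one sample")
  dims <- vapply(samples, function(s) s$ct$grid$dims[1], integer(1))
  if (length(unique(dims)) != 1L) stop("all samples must share one cubic dim")
  model <- build_wingsnet(config, dims[1])
  data <- lapply(samples, sample_input_matrix, config = config)
  opt <- adam_init(model$params)
  hist <- data.frame(step = integer(), loss = numeric(), encoder = numeric(),
                     decoder = numeric(), final = numeric())
  w <- as.numeric(config$loss_weights)
  for (step in seq_len(config$steps)) {
    d <- data[[(step - 1L) %% length(data) + 1L]]
    fwd <- wingsnet_forward(model, d$x)
    ls <- group_loss(list(fwd$enc_pred, fwd$dec_pred), fwd$final, d$ref, w)
    grads <- wingsnet_backward(model, fwd, d$ref, w)
    upd <- adam_step(model$params, grads, opt, config$lr)
    model$params <- upd$params; opt <- upd$state
    hist[step, ] <- list(step, ls$loss, ls$components[1], ls$components[2],
                         ls$components[3])
  }
  if (!is.null(log_csv)) utils::write.csv(hist, log_csv, row.names = FALSE)
  structure(list(model = model, history = hist), class = "wingsnet_fit")
}

#' Predict a 3D dose distribution for a sample
#'
#' Runs the network on the sample's normalized channels, clamps the output
#' at zero and denormalizes to Gy via the sample's prescription.
#'
#' @param model A `wingsnet_model` (e.g. `fit$model`).
#' @param sample A [model_sample()] with the model's input dim.
#' @return An [image_volume()] of kind `"dose_gy"` on the sample grid.
#' @export
predict_dose <- function(model, sample) {
  if (sample$ct$grid$dims[1] != model$input_dim)
    stop("sample dim (", sample$ct$grid$dims[1],
         ") does not match model input dim (", model$input_dim, ")")
  d <- sample_input_matrix(sample, model$config)
  fwd <- wingsnet_forward(model, d$x)
  dose <- denormalize_dose(pmax(fwd$final, 0), sample$prescription_dose)
  image_volume(sample$ct$grid, array(dose, sample$ct$grid$dims),
               kind = "dose_gy")
}

#' Save / load a trained model
#'
#' The checkpoint is a single binary file (R serialization of parameters
#' and config) with a JSON sidecar (`<path>.json`) recording the config,
#' seed and parameter shapes for inspection. `load_wingsnet(save_wingsnet(m))`
#' reproduces predictions bitwise.
#'
#' @param model A `wingsnet_model`.
#' @param path Checkpoint path.
#' @return `path` (save) / the restored `wingsnet_model` (load).
#' @export
save_wingsnet <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config),
               input_dim = model$input_dim), path)
  sidecar <- list(config = unclass(model$config), input_dim = model$input_dim,
                  params = lapply(model$params, function(p)
                    if (is.matrix(p)) dim(p) else length(p)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_wingsnet
#' @export
load_wingsnet <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "wingsnet_config")
  m <- build_wingsnet(cfg, ck$input_dim)
  m$params <- ck$params
  m
}
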