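# Dual adversarial autoencoder for sequences of set-valued visits.
#
# A patient is encoded as a sequence of multi-hot visit vectors over a token
# vocabulary (diagnosis codes + age-band tokens + sex tokens + end-of-sequence
# token). A single-hidden-layer embedder maps each visit set to a dense
# vector, a GRU encoder compresses the sequence to a latent code, and a GRU
# decoder reconstructs per-visit token probabilities. Two feed-forward critics
# make the model "dual adversarial": a latent critic pushes encoder outputs
# toward a standard-normal prior, and a data critic discriminates real
# visit-sequence embeddings from reconstructed ones. Training runs a fixed
# number of epochs (no early stopping); optionally with differentially-private
# per-sample gradient clipping and Gaussian noise on the generator/encoder
# updates (no formal (epsilon, delta) accountant is implemented — the DP
# switch reproduces the mechanics, not a certified guarantee).

#' DAAE configuration
#'
#' Desk-scale defaults are tuned for small simulated cohorts; the full-scale
#' settings used for production-size cohorts are `epochs = 500`,
#' `age_band_width = 1` with `batch_size = 256`.
#'
#' @param latent_dim latent code dimension.
#' @param gru_hidden GRU hidden size (encoder and decoder).
#' @param emb_dim visit-set embedding dimension.
#' @param critic_hidden hidden width of the two critics.
#' @param batch_size minibatch size (default 256).
#' @param epochs fixed training epochs, no early stopping (desk default 50).
#' @param learning_rate Adam step size.
#' @param l2_weight L2 regularization on autoencoder weights.
#' @param pos_weight weight of active tokens in the reconstruction
#'   cross-entropy. Visit vectors are sparse multi-hots (a handful of active
#'   tokens out of the whole vocabulary), so unweighted cross-entropy drives
#'   all probabilities below the 0.5 activation threshold; up-weighting
#'   positives keeps learned token probabilities on the activation side at
#'   their typical positions.
#' @param adv_weight_latent,adv_weight_data weights of the two adversarial
#'   generator updates (0 disables; both 0 reduces the model to a plain
#'   sequence autoencoder).
#' @param latent_noise_sd standard deviation of Gaussian noise added to the
#'   (standardized) latent code during reconstruction training. Smooths the
#'   decoder over the latent neighbourhood of each training sequence so that
#'   draws from the standard-normal prior decode to well-formed records; 0
#'   disables (exact autoencoding, used by the memorization diagnostic).
#' @param max_grad_norm global gradient-norm clip applied to every optimizer
#'   step (adversarial updates in particular can otherwise destabilize the
#'   encoder early in training).
#' @param dp_enabled enable per-sample clipping + Gaussian noise.
#' @param dp_clip_norm,dp_noise_multiplier DP parameters (required iff
#'   `dp_enabled`).
#' @param age_band_width width of age-band tokens in years (desk default 5).
#' @param max_len maximum sequence length L, end-of-sequence slot included;
#'   truncation drops the oldest-age tail.
#' @param seed RNG seed; training is deterministic given seed, config, and
#'   input order.
#' @return a `daae_config` list.
#' @export
daae_config <- function(latent_dim = 8, gru_hidden = 32, emb_dim = 24,
                        critic_hidden = 32, batch_size = 256, epochs = 50,
                        learning_rate = 0.01, l2_weight = 1e-4, pos_weight = 5,
                        adv_weight_latent = 0.02, adv_weight_data = 0.02,
                        latent_noise_sd = 0.6, max_grad_norm = 1,
                        dp_enabled = FALSE, dp_clip_norm = NULL,
                        dp_noise_multiplier = NULL,
                        age_band_width = 5, max_len = 32, seed = 1L) {
  stopifnot(latent_dim > 0, gru_hidden > 0, emb_dim > 0, epochs >= 0,
            max_len >= 2, age_band_width > 0)
  if (dp_enabled && (is.null(dp_clip_norm) || is.null(dp_noise_multiplier)))
    stop("dp_clip_norm and dp_noise_multiplier are required when dp_enabled")
  structure(as.list(environment()), class = "daae_config")
}

token_layout <- function(vocabulary, age_band_width) {
  n_bands <- floor(100 / age_band_width) + 1L
  tokens <- c(vocabulary, paste0("AGE", seq_len(n_bands) - 1L), "SEX_F",
              "SEX_M", "EOS")
  list(tokens = tokens, codes = vocabulary, n_bands = n_bands,
       band_width = age_band_width,
       age_idx = length(vocabulary) + seq_len(n_bands),
       sex_f = length(tokens) - 2L, sex_m = length(tokens) - 1L,
       eos = length(tokens))
}

#' Encode a cohort as padded token sequences
#'
#' Each visit becomes a multi-hot vector of its diagnosis codes plus one
#' age-band token (`band = floor(age / age_band_width)`); the record's sex is
#' prepended as a token in the first visit; an end-of-sequence token is
#' appended after the last visit; sequences longer than `max_len - 1` visits
#' are truncated (dropping the oldest-age tail) and all sequences are padded
#' to length `max_len` with an explicit mask.
#'
#' @param x an `ehr_cohort`.
#' @param config a [daae_config()].
#' @return a `token_sequences` list: binary array `X` (n x L x V), `mask`
#'   (n x L), and the token layout.
#' @export
encode_cohort <- function(x, config) {
  stopifnot(inherits(x, "ehr_cohort"), inherits(config, "daae_config"))
  lay <- token_layout(x$vocabulary, config$age_band_width)
  V <- length(lay$tokens); L <- config$max_len
  n <- length(x$records)
  X <- array(0, dim = c(n, L, V))
  mask <- matrix(0, n, L)
  for (i in seq_len(n)) {
    rec <- x$records[[i]]
    vs <- rec$visits
    if (length(vs) > L - 1L) vs <- vs[seq_len(L - 1L)]
    for (t in seq_along(vs)) {
      v <- vs[[t]]
      ci <- match(v$codes, lay$tokens)
      if (anyNA(ci))
        stop("codes outside vocabulary: ",
             paste(v$codes[is.na(ci)], collapse = ", "))
      X[i, t, ci] <- 1
      ages <- v$ages[!is.na(v$ages)]
      if (length(ages)) {
        band <- pmin(floor(ages / config$age_band_width), lay$n_bands - 1L)
        X[i, t, lay$age_idx[band + 1L]] <- 1
      }
      mask[i, t] <- 1
    }
    if (!is.na(rec$sex))
      X[i, 1, if (rec$sex == "female") lay$sex_f else lay$sex_m] <- 1
    eos_t <- min(length(vs) + 1L, L)
    X[i, eos_t, lay$eos] <- 1
    mask[i, eos_t] <- 1
  }
  structure(list(X = X, mask = mask, layout = lay,
                 anchor_code = x$anchor_code, endpoint_code = x$endpoint_code),
            class = "token_sequences")
}

daae_init_params <- function(V, cfg) {
  list(emb = list(W = init_mat(V, cfg$emb_dim), b = numeric(cfg$emb_dim)),
       enc = gru_params(cfg$emb_dim, cfg$gru_hidden),
       lat = list(W = init_mat(cfg$gru_hidden, cfg$latent_dim),
                  b = numeric(cfg$latent_dim)),
       dec0 = list(W = init_mat(cfg$latent_dim, cfg$gru_hidden),
                   b = numeric(cfg$gru_hidden)),
       # decoder input = previous visit embedding + one-hot step position, so
       # position-locked tokens (sex in the first visit, end-of-sequence) do
       # not regress to the cross-step marginal
       dec = gru_params(cfg$emb_dim + cfg$max_len, cfg$gru_hidden),
       out = list(W = init_mat(cfg$gru_hidden, V), b = numeric(V)))
}

AE_GROUPS <- c("emb", "enc", "lat", "dec0", "dec", "out")
ENC_GROUPS <- c("emb", "enc", "lat")

# slice rows idx from array X (n x L x V) into a list over t of n x V matrices
as_steps <- function(X, idx) {
  L <- dim(X)[2]
  lapply(seq_len(L), function(t) matrix(X[idx, t, ], nrow = length(idx)))
}

embed_steps <- function(p, xs) {
  n <- nrow(xs[[1]])
  lapply(xs, function(x) tanh(x %*% p$emb$W + rep(p$emb$b, each = n)))
}

# full autoencoder forward pass. The raw latent code is standardized per
# batch (running statistics at inference) so that the decoder's input scale
# matches the standard-normal prior it is sampled from; the latent critic then
# only has to shape the standardized distribution.
ae_forward <- function(p, xs, mask, zstats = NULL, z_noise_sd = 0) {
  n <- nrow(xs[[1]]); L <- length(xs)
  es <- embed_steps(p, xs)
  # the encoder consumes the sequence in reverse so that the first visit
  # (which carries the sex token) is adjacent to the final hidden state
  enc <- gru_forward(p$enc, rev(es), mask[, rev(seq_len(L)), drop = FALSE])
  z_raw <- enc$h_last %*% p$lat$W + rep(p$lat$b, each = n)
  if (is.null(zstats)) {
    mu <- colMeans(z_raw)
    sdv <- apply(z_raw, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-3] <- 1
    zstats <- list(mu = mu, sd = sdv)
  }
  z <- sweep(sweep(z_raw, 2, zstats$mu), 2, zstats$sd, "/")
  z_scale <- 1
  if (z_noise_sd > 0) {
    # noise is an additive constant wrt backprop; rescaling keeps the
    # decoder-input distribution at unit variance, matching the prior
    z_scale <- sqrt(1 + z_noise_sd^2)
    z <- (z + matrix(stats::rnorm(length(z), 0, z_noise_sd), nrow(z))) / z_scale
  }
  h0 <- tanh(z %*% p$dec0$W + rep(p$dec0$b, each = n))
  prev <- c(list(matrix(0, n, ncol(es[[1]]))), es[-L])
  dins <- lapply(seq_len(L), function(t) {
    pos <- matrix(0, n, L); pos[, t] <- 1
    cbind(prev[[t]], pos)
  })
  dec <- gru_forward(p$dec, dins, mask, h0 = h0)
  probs <- lapply(dec$hs, function(h) sigm(h %*% p$out$W + rep(p$out$b, each = n)))
  list(es = es, enc = enc, z = z, zstats = zstats, z_scale = z_scale,
       h0 = h0, dins = dins, dec = dec, probs = probs, mask = mask, xs = xs)
}

bce_mean <- function(p, y, w) {
  eps <- 1e-7
  sum(w * -(y * log(p + eps) + (1 - y) * log(1 - p + eps))) / max(sum(w), 1)
}

# reconstruction loss and grads of all autoencoder groups; extra_dz lets the
# caller inject an additional gradient on the latent code. pos_weight
# up-weights active tokens in the per-token cross-entropy.
ae_recon_grads <- function(p, xs, mask, l2 = 0, pos_weight = 1, fw = NULL,
                           dlogits = NULL, extra_dz = NULL, loss_only = FALSE,
                           zstats = NULL, z_noise_sd = 0) {
  if (is.null(fw)) fw <- ae_forward(p, xs, mask, zstats = zstats,
                                    z_noise_sd = z_noise_sd)
  n <- nrow(xs[[1]]); L <- length(xs); V <- ncol(xs[[1]])
  denom <- max(sum(mask), 1) * V
  eps <- 1e-7
  loss <- 0
  for (t in seq_len(L)) {
    pt <- fw$probs[[t]]; yt <- xs[[t]]
    loss <- loss + sum(mask[, t] *
                         -(pos_weight * yt * log(pt + eps) +
                             (1 - yt) * log(1 - pt + eps))) / denom
  }
  if (loss_only) return(list(loss = loss, fw = fw))
  g <- list(out = list(W = p$out$W * 0, b = numeric(length(p$out$b))))
  if (is.null(dlogits)) {
    dlogits <- lapply(seq_len(L), function(t) {
      pt <- fw$probs[[t]]; yt <- xs[[t]]
      ((1 - yt) * pt - pos_weight * yt * (1 - pt)) * mask[, t] / denom
    })
  }
  dhs_dec <- vector("list", L)
  for (t in seq_len(L)) {
    g$out$W <- g$out$W + crossprod(fw$dec$hs[[t]], dlogits[[t]])
    g$out$b <- g$out$b + colSums(dlogits[[t]])
    dhs_dec[[t]] <- dlogits[[t]] %*% t(p$out$W)
  }
  bd <- gru_backward(p$dec, fw$dec, dhs = dhs_dec)
  g$dec <- bd$grads
  dpre_h0 <- bd$dh0 * (1 - fw$h0^2)
  g$dec0 <- list(W = crossprod(fw$z, dpre_h0), b = colSums(dpre_h0))
  dz <- dpre_h0 %*% t(p$dec0$W)
  if (!is.null(extra_dz)) dz <- dz + extra_dz
  dz_raw <- sweep(dz, 2, fw$zstats$sd * fw$z_scale, "/")  # stats as constants
  g$lat <- list(W = crossprod(fw$enc$h_last, dz_raw), b = colSums(dz_raw))
  dh_last <- dz_raw %*% t(p$lat$W)
  be <- gru_backward(p$enc, fw$enc, dh_last = dh_last)
  g$enc <- be$grads
  # embedding grads: encoder inputs (reversed order) and decoder inputs e_{t-1}
  g$emb <- list(W = p$emb$W * 0, b = numeric(length(p$emb$b)))
  d_emb <- ncol(fw$es[[1]])
  for (t in seq_len(L)) {
    de <- be$dxs[[L + 1 - t]]
    if (t < L && !is.null(bd$dxs[[t + 1]]))
      de <- de + bd$dxs[[t + 1]][, seq_len(d_emb), drop = FALSE]
    dpre <- de * (1 - fw$es[[t]]^2)
    g$emb$W <- g$emb$W + crossprod(xs[[t]], dpre)
    g$emb$b <- g$emb$b + colSums(dpre)
  }
  if (l2 > 0) {
    for (gn in AE_GROUPS) for (nm in names(g[[gn]]))
      if (is.matrix(g[[gn]][[nm]]))
        g[[gn]][[nm]] <- g[[gn]][[nm]] + l2 * p[[gn]][[nm]]
  }
  list(loss = loss, grads = g[AE_GROUPS], fw = fw)
}

# masked mean-pooled visit embeddings (one row per record)
pool_embeddings <- function(es, mask) {
  n <- nrow(es[[1]])
  s <- pmax(rowSums(mask), 1)
  acc <- matrix(0, n, ncol(es[[1]]))
  for (t in seq_along(es)) acc <- acc + es[[t]] * mask[, t]
  acc / s
}

# generator-side gradient for fooling the data critic: backprop from the
# pooled reconstructed embedding through the embedder into decoder logits
data_gen_grads <- function(p, xs, mask, fw, dx_pool) {
  n <- nrow(xs[[1]]); L <- length(xs)
  s <- pmax(rowSums(mask), 1)
  ehat <- lapply(fw$probs, function(pt) tanh(pt %*% p$emb$W +
                                               rep(p$emb$b, each = n)))
  g_emb_W <- p$emb$W * 0; g_emb_b <- numeric(length(p$emb$b))
  dlogits <- vector("list", L)
  for (t in seq_len(L)) {
    de <- dx_pool * mask[, t] / s
    dpre <- de * (1 - ehat[[t]]^2)
    g_emb_W <- g_emb_W + crossprod(fw$probs[[t]], dpre)
    g_emb_b <- g_emb_b + colSums(dpre)
    dp <- dpre %*% t(p$emb$W)
    dlogits[[t]] <- dp * fw$probs[[t]] * (1 - fw$probs[[t]]) * mask[, t]
  }
  res <- ae_recon_grads(p, xs, mask, fw = fw, dlogits = dlogits)
  res$grads$emb$W <- res$grads$emb$W + g_emb_W
  res$grads$emb$b <- res$grads$emb$b + g_emb_b
  res$grads
}

clip_to <- function(grads, clip) {
  gn <- global_norm(grads)
  if (gn > clip) scale_grads(grads, clip / gn) else grads
}

# per-sample clipped + noised gradients for the DP optimizer step
dp_grads <- function(compute_one, n, clip, sigma) {
  total <- NULL
  for (i in seq_len(n)) total <- add_grads(total, clip_to(compute_one(i), clip))
  lapply(names(total), function(gn) {
    grp <- total[[gn]]
    lapply(grp, function(m) (m + stats::rnorm(length(m), 0, sigma * clip)) / n)
  }) -> noised
  names(noised) <- names(total)
  noised
}

#' Fit a dual adversarial autoencoder
#'
#' Trains on an encoded cohort for exactly `config$epochs` epochs (no early
#' stopping). Each epoch runs, per minibatch: (a) a reconstruction step
#' minimizing per-token binary cross-entropy on the visit multi-hots; (b) a
#' latent-critic step (critic trained to separate standard-normal prior draws
#' from encoder outputs, then a non-saturating encoder update toward the
#' prior); (c) a data-critic step (critic trained to separate real pooled
#' visit-sequence embeddings from reconstructed ones, then a non-saturating
#' generator update). With `dp_enabled`, the reconstruction (generator/
#' encoder) update uses per-sample gradient clipping at `dp_clip_norm` plus
#' Gaussian noise `dp_noise_multiplier * dp_clip_norm`.
#'
#' @param x an `ehr_cohort` or a `token_sequences` object from
#'   [encode_cohort()].
#' @param config a [daae_config()].
#' @return a `daae` object with the learned parameters, the token layout, and
#'   a per-epoch `loss_trace` data frame (reconstruction, latent-critic and
#'   data-critic losses; `epochs` rows).
#' @export
daae <- function(x, config = daae_config()) {
  seqs <- if (inherits(x, "token_sequences")) x else encode_cohort(x, config)
  X <- seqs$X; mask <- seqs$mask
  n <- dim(X)[1]; V <- dim(X)[3]
  if (n < 1) stop("at least one sequence required")
  set.seed(config$seed)
  p <- daae_init_params(V, config)
  p$dz_critic <- mlp_params(config$latent_dim, config$critic_hidden)
  p$dx_critic <- mlp_params(config$emb_dim, config$critic_hidden)
  opt <- adam_state(p)
  z_stats <- NULL
  tstep <- 0
  trace <- data.frame(epoch = integer(), reconstruction = numeric(),
                      adversarial_latent = numeric(),
                      adversarial_data = numeric())
  check_finite <- function(v, epoch, what) {
    if (!is.finite(v)) stop("non-finite ", what, " loss at epoch ", epoch)
    v
  }
  update <- function(groups, grads) {
    tstep <<- tstep + 1
    grads <- clip_to(grads[groups], config$max_grad_norm)
    for (gn in groups) {
      st <- adam_step(p[[gn]], grads[[gn]], opt[[gn]], config$learning_rate,
                      tstep)
      p[[gn]] <<- st$params
      opt[[gn]] <<- st$state
    }
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_rec <- ep_lat <- ep_dat <- 0
    for (b in batches) {
      xs <- as_steps(X, b); mb <- mask[b, , drop = FALSE]
      nb <- length(b)
      # (a) reconstruction
      if (config$dp_enabled) {
        res <- ae_recon_grads(p, xs, mb, l2 = config$l2_weight,
                              pos_weight = config$pos_weight, loss_only = TRUE,
                              z_noise_sd = config$latent_noise_sd)
        g <- dp_grads(function(i) {
          xi <- lapply(xs, function(m) m[i, , drop = FALSE])
          ae_recon_grads(p, xi, mb[i, , drop = FALSE], l2 = config$l2_weight,
                         pos_weight = config$pos_weight,
                         zstats = res$fw$zstats)$grads
        }, nb, config$dp_clip_norm, config$dp_noise_multiplier)
        update(AE_GROUPS, g)
        rec_loss <- res$loss
        zs <- res$fw$zstats
      } else {
        res <- ae_recon_grads(p, xs, mb, l2 = config$l2_weight,
                              pos_weight = config$pos_weight,
                              z_noise_sd = config$latent_noise_sd)
        update(AE_GROUPS, res$grads)
        rec_loss <- res$loss
        zs <- res$fw$zstats
      }
      z_stats <- if (is.null(z_stats)) zs else
        list(mu = 0.9 * z_stats$mu + 0.1 * zs$mu,
             sd = 0.9 * z_stats$sd + 0.1 * zs$sd)
      ep_rec <- ep_rec + check_finite(rec_loss, epoch, "reconstruction") * nb
      # (b) latent critic + encoder update
      lat_loss <- 0
      if (config$adv_weight_latent > 0) {
        fw <- ae_forward(p, xs, mb)
        zp <- matrix(stats::rnorm(nb * config$latent_dim), nb)
        cin <- rbind(zp, fw$z)
        y <- c(rep(1, nb), rep(0, nb))
        cf <- mlp_forward(p$dz_critic, cin)
        lat_loss <- bce_mean(cf$out, y, rep(1, 2 * nb))
        dlog <- (cf$out - y) / (2 * nb)
        cb <- mlp_backward(p$dz_critic, cf, dlog)
        update("dz_critic", list(dz_critic = cb$grads))
        # encoder: non-saturating, push z toward "prior" label
        cf2 <- mlp_forward(p$dz_critic, fw$z)
        dz <- mlp_backward(p$dz_critic, cf2, (cf2$out - 1) / nb)$dx
        genc <- ae_recon_grads(p, xs, mb, fw = fw,
                               dlogits = lapply(xs, function(m) m * 0),
                               extra_dz = dz)$grads
        update(ENC_GROUPS, scale_grads(genc, config$adv_weight_latent)[ENC_GROUPS])
      }
      ep_lat <- ep_lat + check_finite(lat_loss, epoch, "adversarial-latent") * nb
      # (c) data critic + generator update
      dat_loss <- 0
      if (config$adv_weight_data > 0) {
        fw <- ae_forward(p, xs, mb)
        e_real <- pool_embeddings(fw$es, mb)
        ehat <- lapply(fw$probs, function(pt)
          tanh(pt %*% p$emb$W + rep(p$emb$b, each = nb)))
        e_fake <- pool_embeddings(ehat, mb)
        cin <- rbind(e_real, e_fake)
        y <- c(rep(1, nb), rep(0, nb))
        cf <- mlp_forward(p$dx_critic, cin)
        dat_loss <- bce_mean(cf$out, y, rep(1, 2 * nb))
        dlog <- (cf$out - y) / (2 * nb)
        cb <- mlp_backward(p$dx_critic, cf, dlog)
        update("dx_critic", list(dx_critic = cb$grads))
        cf2 <- mlp_forward(p$dx_critic, e_fake)
        dx_pool <- mlp_backward(p$dx_critic, cf2, (cf2$out - 1) / nb)$dx
        gg <- data_gen_grads(p, xs, mb, fw, dx_pool)
        update(AE_GROUPS, scale_grads(gg, config$adv_weight_data))
      }
      ep_dat <- ep_dat + check_finite(dat_loss, epoch, "adversarial-data") * nb
    }
    trace <- rbind(trace, data.frame(epoch = epoch, reconstruction = ep_rec / n,
                                     adversarial_latent = ep_lat / n,
                                     adversarial_data = ep_dat / n))
  }
  structure(list(params = p, config = config, layout = seqs$layout,
                 anchor_code = seqs$anchor_code,
                 endpoint_code = seqs$endpoint_code,
                 z_stats = z_stats, loss_trace = trace, n_train = n),
            class = "daae")
}

#' @export
print.daae <- function(x, ...) {
  cat(sprintf("<daae> %d tokens, latent %d, GRU %d, trained %d epochs on %d sequences\n",
              length(x$layout$tokens), x$config$latent_dim,
              x$config$gru_hidden, nrow(x$loss_trace), x$n_train))
  invisible(x)
}

#' @export
summary.daae <- function(object, ...) {
  tr <- object$loss_trace
  cat("Dual adversarial autoencoder\n")
  print(object)
  if (nrow(tr)) {
    cat(sprintf("  reconstruction loss: %.4f (epoch 1) -> %.4f (final)\n",
                tr$reconstruction[1], tr$reconstruction[nrow(tr)]))
    cat(sprintf("  final critic losses: latent %.4f, data %.4f\n",
                tr$adversarial_latent[nrow(tr)], tr$adversarial_data[nrow(tr)]))
  } else cat("  untrained (0 epochs)\n")
  invisible(tr)
}

#' @export
plot.daae <- function(x, ...) {
  tr <- x$loss_trace
  if (!nrow(tr)) stop("no loss trace (0 epochs)")
  graphics::matplot(tr$epoch, tr[, -1], type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = names(tr)[-1], col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}

# decode one batch of latent codes greedily; returns list of token index lists
decode_tokens <- function(gen, z) {
  p <- gen$params; cfg <- gen$config; lay <- gen$layout
  n <- nrow(z)
  h <- tanh(z %*% p$dec0$W + rep(p$dec0$b, each = n))
  x_in <- matrix(0, n, nrow(p$emb$W))
  alive <- rep(TRUE, n)
  out <- replicate(n, list(), simplify = FALSE)
  for (t in seq_len(cfg$max_len)) {
    e <- tanh(x_in %*% p$emb$W + rep(p$emb$b, each = n))
    pos <- matrix(0, n, cfg$max_len); pos[, t] <- 1
    step <- gru_forward(p$dec, list(cbind(e, pos)), matrix(1, n, 1), h0 = h)
    h <- step$h_last
    probs <- sigm(h %*% p$out$W + rep(p$out$b, each = n))
    act <- probs >= 0.5
    for (i in which(alive)) {
      if (act[i, lay$eos]) { alive[i] <- FALSE; next }
      out[[i]][[t]] <- list(idx = which(act[i, ]), p = probs[i, ])
    }
    if (!any(alive)) break
    x_in <- act * 1
    x_in[, lay$eos] <- 0
  }
  out
}

tokens_to_record <- function(tok_visits, lay, id) {
  # sex = the sex token emitted with the highest probability at any visit
  # (missing when none is emitted anywhere)
  best_f <- -Inf; best_m <- -Inf
  visits <- list()
  for (t in seq_along(tok_visits)) {
    tv <- tok_visits[[t]]
    if (is.null(tv)) next
    idx <- tv$idx
    if (lay$sex_f %in% idx) best_f <- max(best_f, tv$p[lay$sex_f])
    if (lay$sex_m %in% idx) best_m <- max(best_m, tv$p[lay$sex_m])
    codes <- lay$tokens[idx[idx <= length(lay$codes)]]
    bands <- idx[idx %in% lay$age_idx] - length(lay$codes) - 1L
    ages <- if (length(bands)) bands * lay$band_width + lay$band_width / 2 else
      NA_real_
    age <- if (length(bands) == 1L) ages[1] else NA_real_
    visits[[length(visits) + 1L]] <- visit(age = age, codes = codes,
                                           ages = ages)
  }
  sex <- if (is.infinite(best_f) && is.infinite(best_m)) NA_character_
  else if (best_f >= best_m) "female" else "male"
  patient_record(id = id, sex = sex, visits = visits)
}

#' Sample a raw synthetic cohort from a trained generator
#'
#' Draws latent codes from the standard-normal prior and decodes greedily:
#' per-visit token probabilities are thresholded at 0.5, the sequence ends at
#' the end-of-sequence token or at the maximum length, age-band tokens map
#' back to band midpoints (all raw age labels are retained on the visit), the
#' sex token maps to sex (missing when none is emitted). The output is a *raw*
#' cohort that may carry every defect [refine_cohort()] handles.
#'
#' @param gen a trained `daae`.
#' @param n number of records to sample (`n = 0` gives an empty cohort).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return an `ehr_cohort`.
#' @export
sample_cohort <- function(gen, n, seed = 1L) {
  stopifnot(inherits(gen, "daae"))
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  if (n == 0)
    return(cohort(list(), vocabulary = gen$layout$codes,
                  anchor_code = gen$anchor_code,
                  endpoint_code = gen$endpoint_code))
  z <- matrix(stats::rnorm(n * gen$config$latent_dim), n)
  toks <- decode_tokens(gen, z)
  records <- lapply(seq_len(n), function(i)
    tokens_to_record(toks[[i]], gen$layout, sprintf("s%06d", i)))
  cohort(records, vocabulary = gen$layout$codes,
         anchor_code = gen$anchor_code, endpoint_code = gen$endpoint_code)
}

#' @export
simulate.daae <- function(object, nsim = 1, seed = 1L, ...) {
  sample_cohort(object, n = nsim, seed = seed)
}

#' Deterministic reconstruction of a cohort through the autoencoder
#'
#' Encodes each record to its latent code and decodes greedily; used for
#' round-trip and memorization diagnostics.
#'
#' @param gen a trained `daae`.
#' @param x an `ehr_cohort` encodable with the generator's vocabulary.
#' @return an `ehr_cohort` of reconstructed records (ids preserved).
#' @export
reconstruct <- function(gen, x) {
  stopifnot(inherits(gen, "daae"))
  seqs <- encode_cohort(x, gen$config)
  n <- dim(seqs$X)[1]
  xs <- as_steps(seqs$X, seq_len(n))
  fw <- ae_forward(gen$params, xs, seqs$mask, zstats = gen$z_stats)
  toks <- decode_tokens(gen, fw$z)
  ids <- vapply(x$records, `[[`, "", "id")
  records <- lapply(seq_len(n), function(i)
    tokens_to_record(toks[[i]], gen$layout, ids[i]))
  cohort(records, vocabulary = gen$layout$codes,
         anchor_code = gen$anchor_code, endpoint_code = gen$endpoint_code)
}
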