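# Beta-VAE on canonical tetranucleotide features: mirrored fully-connected
# encoder/decoder, Gaussian (MSE) reconstruction likelihood on standardised
# proportions, reparameterised sampling, Adam, deterministic under a seed.
# Reads are embedded with the encoder mean mu, not sampled z.

#' VAE training configuration
#'
#' Defaults follow the workflow this package implements: a 2D latent space,
#' two hidden layers of 150 units, beta = 0.1, 15 epochs at batch size 256
#' on CPU. beta < 1 is required for the latent space to store useful
#' information about the inputs; beta >= 1 risks posterior collapse and
#' triggers a loud warning rather than an error.
#'
#' @param latent_dim Latent dimensionality (2 for this toolkit).
#' @param hidden_sizes Integer vector of hidden layer widths.
#' @param beta KL weight in the ELBO; must be in (0, 1) to avoid collapse.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling init, shuffling and sampling.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 2L, hidden_sizes = c(150L, 150L),
                       beta = 0.1, epochs = 15L, batch_size = 256L,
                       learning_rate = 1e-3, seed = 1L) {
  if (latent_dim != 2L)
    stop("latent_dim must be 2: the toolkit's visual/peak machinery is 2D")
  if (beta <= 0) stop("beta must be positive")
  if (beta >= 1)
    warning("beta >= 1 risks posterior collapse: the encoder may ignore ",
            "its inputs and match the prior, producing uninformative latents",
            call. = FALSE)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 beta = beta, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "vae_config")
}

#' Preprocess a k-mer count matrix for embedding
#'
#' Counts are converted to per-read proportions (row sum 1) and each column
#' is standardised to mean 0, sd 1 over the dataset. The fitted scaler is
#' returned so new reads can be re-encoded on the same scale; zero-variance
#' columns are centred but not scaled.
#'
#' @param m Count matrix (reads x features), e.g. from [count_matrix()].
#'   Rows with zero total count must be excluded upstream.
#' @param scaler Optional previously fitted scaler to reuse.
#' @return List with `x` (transformed matrix) and `scaler`
#'   (`list(center, scale)`).
#' @export
preprocess_features <- function(m, scaler = NULL) {
  m <- as.matrix(m)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("rows with zero counts must be excluded before embedding: ",
         paste(head(rownames(m)[rs == 0], 3L), collapse = ", "))
  p <- m / rs
  if (is.null(scaler)) {
    center <- colMeans(p)
    scl <- apply(p, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaler <- list(center = center, scale = scl)
  }
  x <- sweep(sweep(p, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
  list(x = x, scaler = scaler)
}

#' Closed-form KL divergence against the unit Gaussian prior
#'
#' For a diagonal Gaussian posterior with mean `mu` and log-variance
#' `logvar`, per row: `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#' Always nonnegative.
#'
#' @param mu Numeric vector or matrix (rows = observations).
#' @param logvar Log-variance, same shape.
#' @return Numeric vector of KL values (one per row).
#' @export
kl_gaussian <- function(mu, logvar) {
  mu <- rbind(mu, deparse.level = 0L)
  logvar <- rbind(logvar, deparse.level = 0L)
  unname(0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar))
}

relu <- function(x) (x > 0) * x

init_params <- function(d_in, hidden, d_lat) {
  sizes_enc <- c(d_in, hidden)
  sizes_dec <- c(d_lat, rev(hidden))
  p <- list()
  mk <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  for (i in seq_along(hidden)) {
    p[[paste0("We", i)]] <- mk(sizes_enc[i], sizes_enc[i + 1L])
    p[[paste0("be", i)]] <- rep(0, sizes_enc[i + 1L])
  }
  hlast <- hidden[length(hidden)]
  p$Wmu <- mk(hlast, d_lat); p$bmu <- rep(0, d_lat)
  p$Wlv <- mk(hlast, d_lat); p$blv <- rep(0, d_lat)
  for (i in seq_along(hidden)) {
    p[[paste0("Wd", i)]] <- mk(sizes_dec[i], sizes_dec[i + 1L])
    p[[paste0("bd", i)]] <- rep(0, sizes_dec[i + 1L])
  }
  p$Wout <- mk(hlast, d_in); p$bout <- rep(0, d_in)
  p
}

addb <- function(m, b) sweep(m, 2L, b, "+")

encoder_forward <- function(p, x, n_hidden) {
  h <- x
  acts <- vector("list", n_hidden)
  for (i in seq_len(n_hidden)) {
    h <- relu(addb(h %*% p[[paste0("We", i)]], p[[paste0("be", i)]]))
    acts[[i]] <- h
  }
  list(mu = addb(h %*% p$Wmu, p$bmu),
       logvar = addb(h %*% p$Wlv, p$blv),
       acts = acts)
}

decoder_forward <- function(p, z, n_hidden) {
  h <- z
  acts <- vector("list", n_hidden)
  for (i in seq_len(n_hidden)) {
    h <- relu(addb(h %*% p[[paste0("Wd", i)]], p[[paste0("bd", i)]]))
    acts[[i]] <- h
  }
  list(xhat = addb(h %*% p$Wout, p$bout), acts = acts)
}

# One minibatch: forward, loss, all gradients. Returns list(loss parts, grads).
vae_batch_grads <- function(p, x, beta, n_hidden) {
  B <- nrow(x)
  enc <- encoder_forward(p, x, n_hidden)
  eps <- matrix(rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
  sd_z <- exp(0.5 * enc$logvar)
  z <- enc$mu + sd_z * eps
  dec <- decoder_forward(p, z, n_hidden)
  resid <- dec$xhat - x
  recon <- sum(resid^2) / (B * ncol(x))   # MSE: mean over batch and features
  kl <- sum(kl_gaussian(enc$mu, enc$logvar)) / B
  g <- list()
  # decoder backprop
  delta <- 2 * resid / (B * ncol(x))           # d loss / d xhat
  hprev <- if (n_hidden > 0) dec$acts[[n_hidden]] else z
  g$Wout <- crossprod(hprev, delta); g$bout <- colSums(delta)
  delta <- delta %*% t(p$Wout)
  for (i in rev(seq_len(n_hidden))) {
    delta <- delta * (dec$acts[[i]] > 0)
    hprev <- if (i > 1L) dec$acts[[i - 1L]] else z
    g[[paste0("Wd", i)]] <- crossprod(hprev, delta)
    g[[paste0("bd", i)]] <- colSums(delta)
    delta <- delta %*% t(p[[paste0("Wd", i)]])
  }
  dz <- delta
  # latent heads: reconstruction path + KL path
  dmu <- dz + beta * enc$mu / B
  dlv <- dz * (0.5 * sd_z * eps) + beta * 0.5 * (exp(enc$logvar) - 1) / B
  hlast <- enc$acts[[n_hidden]]
  g$Wmu <- crossprod(hlast, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(hlast, dlv); g$blv <- colSums(dlv)
  delta <- dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv)
  for (i in rev(seq_len(n_hidden))) {
    delta <- delta * (enc$acts[[i]] > 0)
    hprev <- if (i > 1L) enc$acts[[i - 1L]] else x
    g[[paste0("We", i)]] <- crossprod(hprev, delta)
    g[[paste0("be", i)]] <- colSums(delta)
    delta <- delta %*% t(p[[paste0("We", i)]])
  }
  list(recon = recon, kl = kl, total = recon + beta * kl, grads = g)
}

#' Train a beta-VAE on preprocessed features
#'
#' Mirrored fully-connected encoder/decoder with ReLU activations; loss =
#' mean squared reconstruction error + beta * KL(q(z|x) || N(0, I)),
#' optimised with Adam. Training is deterministic given `config$seed` (fixed
#' initialisation, shuffling and reparameterisation noise).
#'
#' @param features Standardised feature matrix from [preprocess_features()].
#' @param config A [vae_config()].
#' @param scaler Optional scaler to store with the model (so new reads can
#'   be embedded on the training scale).
#' @return An object of class `read_vae`: `params`, `config`, `scaler`,
#'   `history` (per-epoch data frame with `recon`, `kl`, `total`).
#' @export
train_vae <- function(features, config = vae_config(), scaler = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 2L * config$batch_size)
    stop("need at least two batches of data (", 2L * config$batch_size,
         " rows at batch_size ", config$batch_size, "); got ", n,
         " - reduce batch_size")
  n_hidden <- length(config$hidden_sizes)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  p <- init_params(ncol(x), config$hidden_sizes, config$latent_dim)
  m1 <- lapply(p, function(w) w * 0)
  m2 <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- config$learning_rate
  t_step <- 0L
  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), total = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_recon <- ep_kl <- 0; nb <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      res <- vae_batch_grads(p, x[idx, , drop = FALSE], config$beta, n_hidden)
      if (!is.finite(res$total))
        stop("non-finite loss at epoch ", ep,
             "; try a smaller learning_rate")
      t_step <- t_step + 1L
      for (nm in names(p)) {
        gr <- res$grads[[nm]]
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * gr
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * gr^2
        mh <- m1[[nm]] / (1 - b1^t_step)
        vh <- m2[[nm]] / (1 - b2^t_step)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + epsA)
      }
      ep_recon <- ep_recon + res$recon
      ep_kl <- ep_kl + res$kl
      nb <- nb + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, recon = ep_recon / nb,
                                kl = ep_kl / nb,
                                total = (ep_recon + config$beta * ep_kl) / nb))
  }
  structure(list(params = p, config = config, scaler = scaler,
                 history = history),
            class = "read_vae")
}

#' @export
print.read_vae <- function(x, ...) {
  cat(sprintf(
    "read_vae: %d->%s->%d beta=%g, %d epochs (final loss %.3f)\n",
    nrow(x$params$We1), paste(x$config$hidden_sizes, collapse = "-"),
    x$config$latent_dim, x$config$beta, x$config$epochs,
    tail(x$history$total, 1L)))
  invisible(x)
}

#' Encode features to latent means
#'
#' Deterministic pass through the encoder (no sampling): returns the
#' posterior mean `mu` and log-variance per read. `mu` — not a latent
#' sample — is the coordinate used for visualisation, peak finding and
#' selection, as it gives sharper cluster boundaries.
#'
#' @param model A [train_vae()] model.
#' @param features Feature matrix preprocessed with the model's scaler.
#' @return List with matrices `mu` and `logvar` (rows = reads).
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "read_vae"))
  x <- as.matrix(features)
  if (ncol(x) != nrow(model$params$We1))
    stop("feature dimension mismatch: model expects ",
         nrow(model$params$We1), ", got ", ncol(x))
  enc <- encoder_forward(model$params, x, length(model$config$hidden_sizes))
  list(mu = enc$mu, logvar = enc$logvar)
}

#' Train on a count matrix and embed every read
#'
#' Convenience wrapper: preprocesses raw canonical tetranucleotide counts,
#' trains the beta-VAE, and encodes all reads to 2D latent means.
#'
#' @param counts Count matrix from [count_matrix()] (rows named by read id).
#' @param config A [vae_config()].
#' @return List with `model` (a `read_vae` carrying the fitted scaler) and
#'   `embedding` (data frame `id`, `mu1`, `mu2`).
#' @export
embed_reads <- function(counts, config = vae_config()) {
  pp <- preprocess_features(counts)
  model <- train_vae(pp$x, config, scaler = pp$scaler)
  emb <- encode(model, pp$x)
  list(model = model,
       embedding = data.frame(id = rownames(counts),
                              mu1 = emb$mu[, 1L], mu2 = emb$mu[, 2L],
                              stringsAsFactors = FALSE))
}

#' Embed new reads with a trained model
#'
#' @param model A `read_vae` holding a fitted scaler.
#' @param counts Raw count matrix over the same canonical index.
#' @return Data frame `id`, `mu1`, `mu2`.
#' @export
embed_with_model <- function(model, counts) {
  stopifnot(inherits(model, "read_vae"))
  if (is.null(model$scaler)) stop("model carries no scaler")
  pp <- preprocess_features(counts, scaler = model$scaler)
  emb <- encode(model, pp$x)
  data.frame(id = rownames(counts), mu1 = emb$mu[, 1L], mu2 = emb$mu[, 2L],
             stringsAsFactors = FALSE)
}

#' Save / load a trained model as JSON
#'
#' Architecture, weights, scaler and config serialised to one text file.
#'
#' @param model A `read_vae`.
#' @param path Output path.
#' @return `path` (save) or the model (load).
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "read_vae"))
  obj <- list(params = lapply(model$params, function(w) {
    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
    else list(dim = NULL, data = as.numeric(w))
  }),
  config = unclass(model$config), scaler = model$scaler,
  history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(w) {
    if (!is.null(w$dim) && length(w$dim) == 2L) matrix(w$data, w$dim[1L], w$dim[2L])
    else as.numeric(w$data)
  })
  cfg <- obj$config
  config <- suppressWarnings(
    vae_config(cfg$latent_dim, cfg$hidden_sizes, cfg$beta, cfg$epochs,
               cfg$batch_size, cfg$learning_rate, cfg$seed))
  scaler <- if (is.null(obj$scaler)) NULL else
    list(center = as.numeric(obj$scaler$center),
         scale = as.numeric(obj$scaler$scale))
  structure(list(params = params, config = config, scaler = scaler,
                 history = as.data.frame(obj$history)),
            class = "read_vae")
}
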