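#' Fit a variational autoencoder on a feature table
#'
#' A compact multilayer-perceptron VAE over the standardized feature columns
#' plus the target, trained jointly so that sampling the latent prior yields
#' complete synthetic records (features and target together). The encoder
#' maps an input record through tanh hidden layers to a Gaussian posterior
#' `q(z|x) = N(mu(x), diag(exp(logvar(x))))`; the decoder mirrors the hidden
#' stack back to the input space. Training minimizes per-record
#' reconstruction error plus `kl_weight` times the KL divergence of the
#' posterior from the standard-normal prior, with the reparameterization
#' trick and Adam updates. Categorical codes are treated numerically here and
#' snapped back to observed codes at generation time.
#'
#' @param train A preprocessed [feature_table()] with target (>= 50 rows for
#'   training; fewer is an error).
#' @param hidden_dims Sizes of the two hidden layers (encoder order).
#' @param latent_dim Latent dimension.
#' @param epochs Training epochs; 0 returns an untrained (randomly
#'   initialized) state whose prior samples are still finite.
#' @param batch_size Minibatch size.
#' @param kl_weight Weight on the KL term.
#' @param learning_rate Adam step size.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A `vae_state`: network parameters, standardization constants,
#'   column metadata, and the per-epoch `losses` vector.
#' @export
vae_fit <- function(train, hidden_dims = c(32, 16), latent_dim = 8,
                    epochs = 200, batch_size = 32, kl_weight = 1,
                    learning_rate = 1e-3, seed = NULL) {
  if (epochs > 0 && nrow(train) < 50) {
    stop("insufficient data: VAE training needs at least 50 rows", call. = FALSE)
  }
  df <- as.data.frame(train)
  cols <- c(feature_names(train), target_name(train))
  X <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  sd_x[!is.finite(sd_x) | sd_x == 0] <- 1
  Z <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  d <- ncol(Z); h1 <- hidden_dims[1]; h2 <- hidden_dims[2]; L <- latent_dim

  maybe_with_seed(seed, {
    par <- list(
      We1 = xavier(d, h1), be1 = numeric(h1),
      We2 = xavier(h1, h2), be2 = numeric(h2),
      Wmu = xavier(h2, L), bmu = numeric(L),
      Wlv = xavier(h2, L), blv = numeric(L),
      Wd1 = xavier(L, h2), bd1 = numeric(h2),
      Wd2 = xavier(h2, h1), bd2 = numeric(h1),
      Wd3 = xavier(h1, d), bd3 = numeric(d)
    )
    adam <- list(m = lapply(par, function(p) p * 0),
                 v = lapply(par, function(p) p * 0), t = 0)
    losses <- numeric(epochs)
    n <- nrow(Z)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- Z[idx, , drop = FALSE]
        gl <- vae_step(par, B, kl_weight)
        if (!is.finite(gl$loss)) {
          stop("training divergence: non-finite VAE loss", call. = FALSE)
        }
        adam$t <- adam$t + 1
        for (nm in names(par)) {
          g <- gl$grads[[nm]]
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g^2
          mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
          vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
          par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
        ep_loss <- ep_loss + gl$loss; nb <- nb + 1
      }
      losses[ep] <- ep_loss / nb
    }
    if (epochs >= 2 && losses[epochs] >= losses[1]) {
      warning("VAE training loss did not decrease over training")
    }
    cat_cols <- categorical_features(train)
    structure(list(
      par = par, mu_x = mu_x, sd_x = sd_x, columns = cols,
      target = target_name(train), kinds = column_kinds(train),
      cat_codes = lapply(stats::setNames(cat_cols, cat_cols),
                         function(cn) sort(unique(df[[cn]]))),
      target_range = range(df[[target_name(train)]]),
      latent_dim = L, losses = losses
    ), class = "vae_state")
  })
}

xavier <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# one forward/backward pass; returns loss and gradients
vae_step <- function(par, B, klw) {
  nb <- nrow(B)
  H1 <- tanh(sweep(B %*% par$We1, 2, par$be1, "+"))
  H2 <- tanh(sweep(H1 %*% par$We2, 2, par$be2, "+"))
  MU <- sweep(H2 %*% par$Wmu, 2, par$bmu, "+")
  LV <- sweep(H2 %*% par$Wlv, 2, par$blv, "+")
  LV <- pmin(pmax(LV, -10), 10)
  EPS <- matrix(stats::rnorm(nb * ncol(MU)), nb)
  SD <- exp(0.5 * LV)
  ZL <- MU + SD * EPS
  G1 <- tanh(sweep(ZL %*% par$Wd1, 2, par$bd1, "+"))
  G2 <- tanh(sweep(G1 %*% par$Wd2, 2, par$bd2, "+"))
  XH <- sweep(G2 %*% par$Wd3, 2, par$bd3, "+")

  recon <- sum((XH - B)^2) / nb
  kl <- -0.5 * sum(1 + LV - MU^2 - exp(LV)) / nb
  loss <- recon + klw * kl

  dXH <- 2 * (XH - B) / nb
  gWd3 <- t(G2) %*% dXH; gbd3 <- colSums(dXH)
  dG2 <- (dXH %*% t(par$Wd3)) * (1 - G2^2)
  gWd2 <- t(G1) %*% dG2; gbd2 <- colSums(dG2)
  dG1 <- (dG2 %*% t(par$Wd2)) * (1 - G1^2)
  gWd1 <- t(ZL) %*% dG1; gbd1 <- colSums(dG1)
  dZL <- dG1 %*% t(par$Wd1)
  dMU <- dZL + klw * MU / nb
  dLV <- dZL * EPS * 0.5 * SD + klw * 0.5 * (exp(LV) - 1) / nb
  gWmu <- t(H2) %*% dMU; gbmu <- colSums(dMU)
  gWlv <- t(H2) %*% dLV; gblv <- colSums(dLV)
  dH2 <- (dMU %*% t(par$Wmu) + dLV %*% t(par$Wlv)) * (1 - H2^2)
  gWe2 <- t(H1) %*% dH2; gbe2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(par$We2)) * (1 - H1^2)
  gWe1 <- t(B) %*% dH1; gbe1 <- colSums(dH1)

  list(loss = loss, grads = list(
    We1 = gWe1, be1 = gbe1, We2 = gWe2, be2 = gbe2,
    Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
    Wd1 = gWd1, bd1 = gbd1, Wd2 = gWd2, bd2 = gbd2,
    Wd3 = gWd3, bd3 = gbd3
  ))
}

vae_decode <- function(state, Zl) {
  par <- state$par
  G1 <- tanh(sweep(Zl %*% par$Wd1, 2, par$bd1, "+"))
  G2 <- tanh(sweep(G1 %*% par$Wd2, 2, par$bd2, "+"))
  sweep(G2 %*% par$Wd3, 2, par$bd3, "+")
}

#' Generate synthetic records from a fitted VAE
#'
#' Draws `z ~ N(0, I)` from the latent prior, decodes, de-standardizes, and
#' snaps categorical columns to the nearest observed code. Decoded records
#' whose target falls outside the observed training range (widened by
#' `margin` times the range on each side) are rejected and redrawn; each
#' accepted record is assigned to the target bin containing its decoded
#' target. Latent draws are logged in the `draws` attribute.
#'
#' @param state A `vae_state` from [vae_fit()].
#' @param bins A `bin_partition` over the training target.
#' @param n Number of records to generate.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param margin Target acceptance margin as a fraction of the observed
#'   target range (default 0.05).
#' @param max_tries Redraw rounds before giving up and returning fewer rows.
#' @return A [feature_table()] with attributes `bins_assigned` (integer bin
#'   per row) and `draws` (matrix of accepted latent draws).
#' @export
vae_generate <- function(state, bins, n, seed = NULL, margin = 0.05, max_tries = 50) {
  stopifnot(inherits(state, "vae_state"))
  cols <- state$columns
  empty <- function() {
    df <- as.data.frame(matrix(numeric(0), 0, length(cols), dimnames = list(NULL, cols)))
    out <- feature_table(df, target = state$target, kinds = state$kinds)
    attr(out, "bins_assigned") <- integer(0)
    attr(out, "draws") <- matrix(0, 0, state$latent_dim)
    out
  }
  if (n == 0) return(empty())
  rng <- state$target_range
  m <- margin * (rng[2] - rng[1])
  maybe_with_seed(seed, {
    acc <- list(); zacc <- list(); got <- 0L; tries <- 0L
    while (got < n && tries < max_tries) {
      tries <- tries + 1L
      draw <- max(n - got, 1L)
      Zl <- matrix(stats::rnorm(draw * state$latent_dim), draw)
      D <- vae_decode(state, Zl)
      X <- sweep(sweep(D, 2, state$sd_x, "*"), 2, state$mu_x, "+")
      colnames(X) <- cols
      yv <- X[, state$target]
      keep <- is.finite(yv) & yv >= rng[1] - m & yv <= rng[2] + m
      if (any(keep)) {
        acc[[length(acc) + 1L]] <- X[keep, , drop = FALSE]
        zacc[[length(zacc) + 1L]] <- Zl[keep, , drop = FALSE]
        got <- got + sum(keep)
      }
    }
    if (got == 0) return(empty())
    X <- do.call(rbind, acc)[seq_len(min(got, n)), , drop = FALSE]
    Zl <- do.call(rbind, zacc)[seq_len(min(got, n)), , drop = FALSE]
    df <- as.data.frame(X)
    for (cn in names(state$cat_codes)) {
      codes <- state$cat_codes[[cn]]
      df[[cn]] <- vapply(df[[cn]], function(v) codes[which.min(abs(codes - v))], numeric(1))
    }
    out <- feature_table(df, target = state$target, kinds = state$kinds)
    attr(out, "bins_assigned") <- bin_assign(bins$edges, df[[state$target]])
    attr(out, "draws") <- Zl
    out
  })
}
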