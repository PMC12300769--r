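#' Stratified dual-pipeline data augmentation with iterative quality control
#'
#' The core augmentation procedure: bins the training target adaptively
#' ([make_bins()]), plans per-bin synthetic quotas toward the largest bin
#' ([plan_quotas()]), then iteratively generates candidates through two
#' pipelines — SMOTER interpolation ([smote_generate()]) for a `smote_share`
#' fraction and a VAE ([vae_fit()], [vae_generate()]) for the remainder —
#' and quality-controls every candidate before crediting it against its
#' bin's quota:
#'
#' * every continuous feature must lie inside its assigned bin's observed
#'   envelope widened by `qc_margin` times the per-bin range;
#' * the target must lie inside the bin's edges widened by `target_margin`
#'   times the bin width.
#'
#' Rounds continue until all quotas are met or `max_rounds` is reached; bins
#' whose quota cannot be filled leave a warning and a partial augmentation,
#' never an error. Bins with fewer than 2 donor rows route their quota to the
#' VAE pipeline. In the final two rounds the SMOTER pipeline covers any
#' remaining quota in bins that have donors, so that reachable quotas are
#' actually met. The output concatenates the original rows and the accepted
#' synthetic rows with a `.provenance` column (`original`, `smote`, `vae`).
#'
#' @param train A preprocessed [feature_table()] with target.
#' @param config An [sdml_config()]; the `augment` and `vae` blocks are used.
#' @param seed Integer seed; the whole loop (VAE training included) runs
#'   under it, so identical inputs give identical output.
#' @return A list with `table` (augmented [feature_table()] with
#'   `.provenance`), `bins` (the quota-filled partition) and `report`
#'   (per-bin before/after counts, acceptance rates, target mean/std drift).
#' @export
#' @examples
#' sim <- simulate_dataset(generator_spec(n = 80, seed = 2))
#' aug <- augment_dataset(sim$table,
#'                        config = sdml_config(augment = list(expansion_factor = 2),
#'                                             vae = list(epochs = 30)),
#'                        seed = 1)
#' nrow(aug$table) / nrow(sim$table)
augment_dataset <- function(train, config = sdml_config(), seed = 1) {
  ac <- config$augment
  vc <- config$vae
  tn <- target_name(train)
  sdml_log("augment_dataset: config %s, %d rows in", config_hash(config), nrow(train))
  y <- target_values(train)
  bins <- make_bins(y, skew_threshold = ac$bin_skew_threshold)
  bins <- plan_quotas(bins, ac$expansion_factor)
  df <- as.data.frame(train)
  cont <- continuous_features(train)
  assign_orig <- bin_assign(bins$edges, y)

  # per-bin, per-feature acceptance envelopes
  glob_rng <- vapply(df[cont], function(v) diff(range(v)), numeric(1))
  env_lo <- env_hi <- matrix(NA_real_, bins$n_bins, length(cont),
                             dimnames = list(NULL, cont))
  for (b in seq_len(bins$n_bins)) {
    rows_b <- which(assign_orig == b)
    for (f in seq_along(cont)) {
      v <- df[rows_b, cont[f]]
      lo <- min(v); hi <- max(v)
      m <- ac$qc_margin * (hi - lo)
      if (m == 0) m <- ac$qc_margin * glob_rng[f]
      env_lo[b, f] <- lo - m; env_hi[b, f] <- hi + m
    }
  }
  widths <- diff(bins$edges)

  qc_pass <- function(cand_df, bin_idx) {
    if (nrow(cand_df) == 0) return(logical(0))
    ok <- rep(TRUE, nrow(cand_df))
    Xc <- as.matrix(cand_df[, cont, drop = FALSE])
    for (f in seq_along(cont)) {
      ok <- ok & Xc[, f] >= env_lo[bin_idx, f] & Xc[, f] <= env_hi[bin_idx, f]
    }
    yv <- cand_df[[tn]]
    lo <- bins$edges[bin_idx] - ac$target_margin * widths[bin_idx]
    hi <- bins$edges[bin_idx + 1] + ac$target_margin * widths[bin_idx]
    ok & yv >= lo & yv <= hi
  }

  total_quota <- sum(bins$quota)
  donors_per_bin <- tabulate(assign_orig, nbins = bins$n_bins)
  smote_ok <- donors_per_bin >= 2

  accepted <- list()
  acc_bin <- integer(0)
  acc_src <- character(0)
  n_gen <- c(smote = 0, vae = 0)
  n_acc <- c(smote = 0, vae = 0)

  withr::with_seed(seed, {
    use_vae <- ac$smote_share < 1 && total_quota > 0 && nrow(train) >= 50
    vae_state <- if (use_vae) {
      vae_fit(train, hidden_dims = vc$hidden_dims, latent_dim = vc$latent_dim,
              epochs = vc$epochs, batch_size = vc$batch_size,
              kl_weight = vc$kl_weight, learning_rate = vc$learning_rate,
              seed = NULL)
    } else NULL

    remaining <- bins$quota
    round_i <- 0L
    while (sum(remaining) > 0 && round_i < ac$max_rounds) {
      round_i <- round_i + 1L
      final_push <- round_i > ac$max_rounds - 2L || is.null(vae_state)
      share <- if (final_push) 1 else ac$smote_share
      smote_target <- remaining
      smote_target[!smote_ok] <- 0L
      n_smote <- round_half_up(share * sum(smote_target))
      n_vae <- sum(remaining) - n_smote

      if (n_smote > 0 && any(smote_target > 0)) {
        bq <- bins; bq$quota <- as.integer(smote_target)
        cand <- smote_generate(train, bq, k_neighbors = ac$k_neighbors,
                               noise_scale = ac$noise_scale, n = n_smote, seed = NULL)
        cb <- attr(cand, "draws")$bin
        n_gen["smote"] <- n_gen["smote"] + nrow(cand)
        ok <- qc_pass(as.data.frame(cand), cb)
        for (b in unique(cb[ok])) {
          take <- which(ok & cb == b)
          take <- take[seq_len(min(length(take), remaining[b]))]
          if (!length(take)) next
          accepted[[length(accepted) + 1L]] <- as.data.frame(cand)[take, , drop = FALSE]
          acc_bin <- c(acc_bin, rep(b, length(take)))
          acc_src <- c(acc_src, rep("smote", length(take)))
          n_acc["smote"] <- n_acc["smote"] + length(take)
          remaining[b] <- remaining[b] - length(take)
        }
      }
      if (!is.null(vae_state) && n_vae > 0) {
        cand <- vae_generate(vae_state, bins, n = n_vae, seed = NULL,
                             margin = ac$qc_margin)
        cb <- attr(cand, "bins_assigned")
        n_gen["vae"] <- n_gen["vae"] + nrow(cand)
        if (nrow(cand)) {
          ok <- qc_pass(as.data.frame(cand), cb)
          for (b in unique(cb[ok])) {
            if (remaining[b] <= 0) next
            take <- which(ok & cb == b)
            take <- take[seq_len(min(length(take), remaining[b]))]
            if (!length(take)) next
            accepted[[length(accepted) + 1L]] <- as.data.frame(cand)[take, names(df), drop = FALSE]
            acc_bin <- c(acc_bin, rep(b, length(take)))
            acc_src <- c(acc_src, rep("vae", length(take)))
            n_acc["vae"] <- n_acc["vae"] + length(take)
            remaining[b] <- remaining[b] - length(take)
          }
        }
      }
    }
    if (sum(remaining) > 0) {
      warning(sprintf("augmentation quota unmet after %d rounds: %d of %d synthetic rows missing",
                      round_i, sum(remaining), total_quota))
    }

    syn_df <- if (length(accepted)) do.call(rbind, accepted) else df[0, , drop = FALSE]
    out_df <- rbind(cbind(df, .provenance = "original"),
                    cbind(syn_df, .provenance = acc_src))
    rownames(out_df) <- NULL

    after_counts <- donors_per_bin + tabulate(acc_bin, nbins = bins$n_bins)
    drift <- vapply(seq_len(bins$n_bins), function(b) {
      ya <- out_df[[tn]][bin_assign(bins$edges, out_df[[tn]]) == b]
      if (!length(ya) || is.na(bins$stats$mean[b])) return(NA_real_)
      mean(ya) - bins$stats$mean[b]
    }, numeric(1))
    report <- list(
      per_bin = data.frame(bin = seq_len(bins$n_bins),
                           n_before = donors_per_bin,
                           quota = bins$quota,
                           n_after = after_counts,
                           mean_before = bins$stats$mean,
                           std_before = bins$stats$std,
                           mean_drift = drift),
      n_generated = n_gen, n_accepted = n_acc,
      acceptance_rate = ifelse(n_gen > 0, n_acc / n_gen, NA_real_),
      rounds = round_i,
      quota_met = sum(remaining) == 0,
      balance_before = min(donors_per_bin) / max(donors_per_bin),
      balance_after = min(after_counts) / max(after_counts),
      vae_losses = if (!is.null(vae_state)) vae_state$losses else NULL
    )
    out <- feature_table(out_df, target = tn, kinds = column_kinds(train))
    sdml_log("augment_dataset: %d -> %d rows (%d synthetic)", nrow(df), nrow(out_df),
             nrow(out_df) - nrow(df))
    list(table = out, bins = bins, report = report)
  })
}
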