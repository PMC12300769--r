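#' Default run configuration
#'
#' All stage parameters of the workflow in one nested list. Values here are
#' the package defaults; any subset can be overridden through `...` using
#' nested lists, e.g. `sdml_config(augment = list(expansion_factor = 4))`.
#'
#' Key defaults: 75/25 train/test split; skewness threshold 1 for log
#' transforms; equal composite weights over the five dependence statistics;
#' augmentation expansion factor 9 (final size = 9 x original training size)
#' split evenly between the SMOTER and VAE pipelines; SMOTE k = 5 neighbours
#' with noise scale 0.02; VAE with hidden layers (32, 16), 8 latent units,
#' 200 epochs; 5-fold cross-validation and a 50-trial tuning budget; GP with
#' population 2000 over 100 generations.
#'
#' @param ... Named nested overrides, merged recursively into the defaults.
#' @return A nested list of class `sdml_config`.
#' @export
sdml_config <- function(...) {
  cfg <- list(
    split = list(train_fraction = 0.75, seed = 1),
    preprocess = list(
      skew_threshold = 1, shift_eps = 1e-6,
      impute_trees = 100, impute_tol = 1e-3, impute_max_rounds = 10
    ),
    features = list(
      weights = c(f_stat = 0.2, mutual_info = 0.2, dist_corr = 0.2,
                  mic = 0.2, relieff = 0.2),
      n_bootstrap = 100, bootstrap_fraction = 0.8, vif_cap = 10,
      mi_k = 3, relieff_k = 10,
      base_features = c("MW", "logKow", "pKa", "TPSA", "ExposureTime")
    ),
    augment = list(
      expansion_factor = 9, smote_share = 0.5, k_neighbors = 5,
      noise_scale = 0.02, bin_skew_threshold = 1,
      qc_margin = 0.05, target_margin = 0.1, max_rounds = 20
    ),
    vae = list(
      hidden_dims = c(32, 16), latent_dim = 8, epochs = 200,
      batch_size = 32, kl_weight = 1, learning_rate = 1e-3
    ),
    models = list(n_folds = 5, budget = 50),
    symreg = list(
      gp = list(pop = 2000, gens = 100, parsimony = 0.001,
                tournament = 20, p_crossover = 0.7, p_mutation = 0.2),
      mftec = list(m = 8),
      hsie = list(max_order = 3, dict_cap = 20000)
    )
  )
  merge_cfg(cfg, list(...))
}

merge_cfg <- function(base, over) {
  rec <- function(b, o) {
    for (nm in names(o)) {
      b[[nm]] <- if (is.list(o[[nm]]) && is.list(b[[nm]])) rec(b[[nm]], o[[nm]]) else o[[nm]]
    }
    b
  }
  base <- rec(base, over)
  class(base) <- "sdml_config"
  base
}

#' Write / read a run configuration
#'
#' Configurations serialize to a nested YAML file. Reading normalizes scalar
#' types against the default schema so a write/read round trip is
#' value-lossless.
#'
#' @param cfg An [sdml_config()] list.
#' @param path File path.
#' @return `config_read` returns an `sdml_config`; `config_write` returns
#'   `path` invisibly.
#' @export
config_write <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  norm <- function(ref, val) {
    if (is.list(ref)) {
      out <- ref
      for (nm in names(ref)) {
        if (nm %in% names(val)) out[[nm]] <- norm(ref[[nm]], val[[nm]])
      }
      extra <- setdiff(names(val), names(ref))
      out[extra] <- val[extra]
      return(out)
    }
    v <- unlist(val, use.names = FALSE)
    if (is.numeric(ref)) v <- as.numeric(v)
    if (!is.null(names(ref)) && length(v) == length(ref)) names(v) <- names(ref)
    v
  }
  cfg <- norm(unclass(sdml_config()), raw)
  class(cfg) <- "sdml_config"
  cfg
}

# FNV-1a-style hash of a deparsed config, for run logging; arithmetic kept
# inside the exactly-representable double range
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # h * 16777619 mod 2^32 in two 16-bit halves to stay exact in doubles
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
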