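#' Default run configuration
#'
#' Every tunable used by the pipeline, with its default. Loss weights default
#' to lambda1 = 0.1, lambda2 = 0.5, lambda3 = 0.1; the focal exponents default
#' to alpha = 2, beta = 4 and the contrastive temperature to t = 0.07.
#' `pi_p = NA` means the positive-class prior is estimated at training time
#' as the expected particle volume fraction (expected_particles x
#' expected_radius ball volume / volume size).
#'
#' @return a named list of class `run_config`.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 0L,
    # candidate proposal
    expected_radius = 4, denoise_sigma = 2, hist_bins = 256L,
    dog_levels = 3L, dog_sigma_ratio = 1.6, nms_radius = 4,
    max_candidates = 2000L, patch_side = 32L, angle_window = 15,
    invert_contrast = TRUE,
    # exploration network
    embed_dim = 128L, backbone_stages = 2L, backbone_channels = 8L,
    explore_batch = 16L, explore_steps = 30L, explore_lr = 0.02,
    momentum = 0.9, weight_decay = 1e-4,
    flip_prob = 0.5, brightness_max = 0.5, contrast_max = 0.2,
    crop_scale_min = 0.7, corner_frac_min = 0.1, corner_frac_max = 0.25,
    rotate90 = TRUE,
    # embedding space
    umap_neighbors = 40L, umap_min_dist = 0.1,
    kmeans_k = 50L, spectral_h = 10L,
    # detector
    mode = "globular", detect_rescale = "standardize",
    detect_wedge_filter = 60,
    sigma_k = 2, tube_label_radius = 3,
    alpha = 2, beta = 4, temperature = 0.07,
    pi_p = NA_real_, pi_tp = 0.5, expected_particles = 30L,
    lambda1 = 0.1, lambda2 = 0.5, lambda3 = 0.1,
    pseudo_pos_threshold = 0.9, pseudo_neg_threshold = 0.3,
    unet_blocks = 2L, unet_channels = 8L, slice_context = 2L,
    fusion_channels = 16L,
    contrast_channels = 16L,
    crop_xy = 64L, crop_z = 5L, detect_batch = 2L,
    detect_epochs = 15L, steps_per_epoch = 16L,
    detect_lr = 3e-3, lr_decay_factor = 10, lr_decay_every = 8L,
    contrast_subsample = 128L,
    nms_kernel = 9L, prob_threshold = 0.85,
    ablate_contrastive = FALSE, ablate_pu = FALSE,
    # tube post-processing
    tube_cutoff = 6, residual_cutoff = 1.5, curvature_cutoff = 0.1,
    resample_step = 2,
    # evaluation
    match_radius = 4
  )
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, what)
    if (!isTRUE(ok)) stop("config value out of range: ", what, call. = FALSE)
  pos <- c("expected_radius", "dog_sigma_ratio", "nms_radius", "patch_side",
           "angle_window", "embed_dim", "backbone_stages", "backbone_channels",
           "explore_batch", "explore_steps", "sigma_k", "tube_label_radius",
           "alpha", "beta", "temperature", "unet_blocks", "unet_channels",
           "fusion_channels", "contrast_channels", "crop_xy", "crop_z",
           "detect_batch", "steps_per_epoch", "lr_decay_factor",
           "lr_decay_every", "contrast_subsample", "nms_kernel",
           "tube_cutoff", "residual_cutoff", "curvature_cutoff",
           "resample_step", "match_radius", "expected_particles")
  for (k in pos) chk(is.numeric(cfg[[k]]) && cfg[[k]] > 0, k)
  nonneg <- c("denoise_sigma", "explore_lr", "detect_lr", "momentum",
              "weight_decay", "lambda1", "lambda2", "lambda3",
              "detect_epochs", "max_candidates", "slice_context")
  for (k in nonneg) chk(is.numeric(cfg[[k]]) && cfg[[k]] >= 0, k)
  prob <- c("flip_prob", "brightness_max", "contrast_max", "crop_scale_min",
            "corner_frac_min", "corner_frac_max", "umap_min_dist",
            "pseudo_pos_threshold", "pseudo_neg_threshold", "prob_threshold")
  for (k in prob) chk(is.numeric(cfg[[k]]) && cfg[[k]] >= 0 && cfg[[k]] <= 1, k)
  if (!is.na(cfg$pi_p)) chk(cfg$pi_p > 0 && cfg$pi_p < 1, "pi_p")
  if (!is.na(cfg$pi_tp)) chk(cfg$pi_tp > 0 && cfg$pi_tp <= 1, "pi_tp")
  chk(cfg$mode %in% c("globular", "tubular"), "mode")
  chk(cfg$detect_rescale %in% c("standardize", "equalize"), "detect_rescale")
  if (is.finite(cfg$detect_wedge_filter))
    chk(cfg$detect_wedge_filter > 0 && cfg$detect_wedge_filter <= 90,
        "detect_wedge_filter")
  chk(cfg$spectral_h <= cfg$kmeans_k, "spectral_h (must be <= kmeans_k)")
  chk(cfg$nms_kernel %% 2 == 1, "nms_kernel (must be odd)")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys fall back to [default_config()]; unknown keys and
#' out-of-range values raise an error naming the offending key.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(user)) {
      tmpl <- cfg[[k]]
      cfg[[k]] <- if (is.integer(tmpl)) as.integer(user[[k]])
                  else if (is.numeric(tmpl)) as.numeric(user[[k]])
                  else if (is.logical(tmpl)) as.logical(user[[k]])
                  else user[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' Round-trips exactly through [load_config()].
#'
#' @param cfg a `run_config` list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
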