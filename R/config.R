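# Configuration: one nested default tree, YAML/JSON overlays validated
# against it (unknown keys rejected, scalar types checked).

#' Default configuration tree
#'
#' @return nested list with sections `generate`, `model`, `loss`,
#'   `postprocess`, `train`.
#' @export
default_config <- function() {
  list(
    generate = list(height = 256L, width = 256L, n_nuclei = 20L, n_types = 4L,
                    overlap_fraction = 0.3, noise_sd = 0.02),
    model = list(width = 64L, input_size = 270L, n_classes = 4L,
                 use_transformer = TRUE, simam_res = TRUE, simam_des = TRUE,
                 simam_lambda = 1e-4,
                 transformer = list(n_layers = 12L, embed_dim = 768L,
                                    n_heads = 12L, mlp_dim = 3072L,
                                    patch_edge = 8L)),
    loss = list(lambda_a = 1, lambda_b = 2, lambda_c = 1, lambda_d = 1,
                lambda_e = 1, lambda_f = 1, sobel_ksize = 5L),
    postprocess = list(h = 0.5, k = 0.4, sobel_ksize = 5L, min_size = 10L),
    train = list(stage1_epochs = 50L, stage2_epochs = 100L,
                 batch_size_stage1 = 8L, batch_size_stage2 = 4L,
                 lr_initial = 1e-4, lr_after = 1e-5, lr_switch_epoch = 25L,
                 flip = TRUE, rotation = TRUE, gaussian_blur = TRUE,
                 median_blur = TRUE)
  )
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key", if (length(unknown) > 1L) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    key <- paste0(path, k)
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_validate(defaults[[k]], user[[k]], paste0(key, "."))
    } else {
      v <- user[[k]]
      if (length(v) != 1L) stop("config key '", key, "' must be a scalar")
      if (is.logical(defaults[[k]])) {
        if (!is.logical(v)) stop("config key '", key, "' must be logical, got ",
                                 class(v)[1])
      } else if (is.numeric(defaults[[k]])) {
        if (!is.numeric(v)) stop("config key '", key, "' must be numeric, got ",
                                 class(v)[1])
      }
      defaults[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else v
    }
  }
  defaults
}

#' Load and validate a configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file, overlays it on
#' [default_config()], rejects unknown keys, and checks scalar types. An
#' empty or missing file gives pure defaults.
#'
#' @param path config file path, or `NULL` for defaults.
#' @return validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension '", ext, "' (use .yaml/.yml/.json)")
  }
  if (length(user) == 0L) return(defaults)
  merge_validate(defaults, user)
}

#' Build a model from a configuration tree
#' @param config nested list as from [load_config()].
#' @param seed weight-initialization seed.
#' @return a `hovseg_model`.
#' @export
model_from_config <- function(config, seed = 1L) {
  mc <- config$model
  tfc <- mc$transformer
  build_model(
    trunk = trunk_config(width = mc$width, input_size = mc$input_size),
    tf = transformer_config(n_layers = tfc$n_layers, embed_dim = tfc$embed_dim,
                            n_heads = tfc$n_heads, mlp_dim = tfc$mlp_dim,
                            patch_edge = tfc$patch_edge),
    branches = default_branches(mc$n_classes),
    use_transformer = mc$use_transformer, simam_res = mc$simam_res,
    simam_des = mc$simam_des, simam_lambda = mc$simam_lambda, seed = seed)
}

#' Post-processing parameters from a configuration tree
#' @param config nested list as from [load_config()].
#' @return a [postprocess_params()].
#' @export
postprocess_params_from_config <- function(config) {
  pc <- config$postprocess
  postprocess_params(h = pc$h, k = pc$k, sobel_ksize = pc$sobel_ksize,
                     min_size = pc$min_size)
}
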