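# YAML-backed run configuration: defaults, strict validation (unknown keys
# rejected), merge with CLI overrides.

#' Default run configuration
#'
#' The full configuration tree consumed by the command-line pipeline. Keys
#' mirror the package's module options: `data` (phantom dataset), `synthesis`
#' (Stage I), `diffusion`/`guidance` (Stage II), `loss`/`train` (Stage III),
#' and `eval`.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    data = list(size = 32L, n_train = 60L, n_test_normal = 20L,
                n_test_fractured = 20L),
    synthesis = list(beta_range = c(0.5, 1.0), thickness = 1L, ratio = 0.5,
                     augment_shape = TRUE),
    diffusion = list(T = NULL, beta_min = 1e-4, beta_max = 0.02),
    guidance = list(w1 = 0.5, w2 = 0.5, triple = NULL, mode = "fixed",
                    reuse_noise = TRUE),
    loss = list(alpha = 0.75, gamma_focal_start = 2, gamma_focal_end = 3.5,
                gamma_mask = 1.0),
    train = list(batch = 16L, lr = NULL, epochs = NULL, steps = NULL,
                 seed = 0L, profile = "desk"),
    eval = list(K = 50L, fpr_cap = 0.3, max_levels = 256L)
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref))
      stop_invalid(sprintf("unknown config key: %s%s", path, nm))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (if given), rejects unknown keys, and merges it over
#' the defaults, then merges explicit overrides on top.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional nested list of overrides.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io(sprintf("no config file at %s", path))
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      check_known_keys(user, cfg)
      cfg <- utils::modifyList(cfg, user)
    }
  }
  if (length(overrides)) {
    check_known_keys(overrides, cfg)
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg
}

write_config_snapshot <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(cfg)
}
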