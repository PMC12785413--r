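# Shared validation helpers and small numeric utilities.

scafdl_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("scafdl_", class), "scafdl_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid <- function(msg) scafdl_error("invalid_argument", msg)
stop_degenerate <- function(msg) scafdl_error("degenerate_input", msg)
stop_io <- function(msg) scafdl_error("io", msg)
stop_metric <- function(msg) scafdl_error("undefined_metric", msg)
stop_validation <- function(msg) scafdl_error("validation", msg)

check_gray <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(sprintf("%s must be a numeric matrix", name))
  if (anyNA(x) || min(x) < -1e-8 || max(x) > 1 + 1e-8)
    stop_invalid(sprintf("%s values must lie in [0, 1]", name))
  invisible(x)
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_invalid(sprintf("%s must have identical dimensions", what))
  invisible(NULL)
}

check_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop_invalid(sprintf("%s must be a matrix", name))
  v <- as.vector(m)
  if (!all(v %in% c(0, 1, FALSE, TRUE)))
    stop_invalid(sprintf("%s must be binary (0/1)", name))
  invisible(m)
}

as_mask <- function(m) {
  storage.mode(m) <- "double"
  m
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic derived seeds, kept below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + (as.double(p) %% 2147483647) + 1) %% 2147483629
  as.integer(h)
}
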