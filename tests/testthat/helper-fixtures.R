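# Shared fixtures, built in code at test time.

desk_phantom <- function(seed = 1, size = 32) generate_phantom(seed, size)

tiny_bank <- function(seed = 5, n = 4, size = 32) {
  generate_texture_bank(seed, n, size)
}

tiny_schedule <- function(T_steps = 200) build_schedule(T_steps)

# Brute-force pairwise AUROC oracle (ties counted one half).
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Per-pixel loop recomputation of one PRO/FPR point.
pro_point_loop <- function(items, thr) {
  pro <- c(); fp <- 0; neg <- 0
  for (it in items) {
    P <- matrix(0, nrow(it$M_hat), ncol(it$M_hat))
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
      if (it$M_hat[i, j] > thr) P[i, j] <- 1
    if (it$label == 1) pro <- c(pro, sum(P == 1 & it$G == 1) / sum(it$G))
    fp <- fp + sum(P == 1 & it$G == 0)
    neg <- neg + sum(it$G == 0)
  }
  c(pro = mean(pro), fpr = fp / neg)
}

# A fast-but-tiny trained bundle shared across tests that need one
# (built lazily, cached for the session).
smoke_bundle_env <- new.env()
smoke_bundle <- function() {
  if (is.null(smoke_bundle_env$bundle)) {
    dir <- file.path(tempdir(), "scafdl-smoke-ds")
    if (!file.exists(file.path(dir, "manifest.json"))) {
      smoke_bundle_env$manifest <- build_dataset(dir, 16, 4, 4, seed = 42, size = 32)
    } else {
      smoke_bundle_env$manifest <- read_manifest(dir)
    }
    smoke_bundle_env$bundle <- train_scafdl(
      smoke_bundle_env$manifest, "desk", seed = 42, steps = 40)
  }
  list(bundle = smoke_bundle_env$bundle, manifest = smoke_bundle_env$manifest)
}
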