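# Shared fixtures: everything is generated in code at test time.

# A small but valid task design (balanced, fast to render).
small_design <- function(n_trials = 8)
  task_design(n_blocks = 1, trials_per_block = n_trials)

# Noise-free ground truth with symmetric, clean lateralized components.
clean_truth <- function(...)
  ground_truth(noise_sd_uv = 0, eog_noise_sd_uv = 0, ...)

# Mirror a schedule across the vertical midline: cued locations 1<->4,
# 2<->3, and the per-location flash-onset columns swapped to match, so a
# mirrored recording is the exact left/right reflection of the original.
mirror_schedule <- function(sch) {
  out <- sch
  out$location <- 5L - sch$location
  for (k in 1:2) {
    out[[paste0("f1_", k)]] <- sch[[paste0("f4_", k)]]
    out[[paste0("f4_", k)]] <- sch[[paste0("f1_", k)]]
    out[[paste0("f2_", k)]] <- sch[[paste0("f3_", k)]]
    out[[paste0("f3_", k)]] <- sch[[paste0("f2_", k)]]
  }
  out
}

# Build a bare recording around a given data matrix (test doubles for the
# preprocessing operations).
make_recording <- function(data, fs = 512, events = NULL) {
  if (is.null(events))
    events <- data.frame(sample = integer(0), kind = character(0),
                         location = integer(0), cued = integer(0))
  erpdecode:::new_recording(data, fs, events)
}

# Build an epoch_set directly from an epoch x channel x sample array.
make_epochs <- function(data, fs = 512, lock = "cue",
                        cued = rep(1L, dim(data)[1]),
                        location = cued, window_ms = c(-200, 800)) {
  n_pre <- round(-window_ms[1] / 1000 * fs)
  structure(list(
    data = data, channels = dimnames(data)[[2]], fs = fs,
    times = (seq_len(dim(data)[3]) - 1 - n_pre) / fs, lock = lock,
    info = data.frame(epoch = seq_len(dim(data)[1]),
                      sample = seq_len(dim(data)[1]), kind = lock,
                      location = location, cued = cued,
                      kept = TRUE, reason = NA_character_)),
    class = "epoch_set")
}

# Zero-filled epoch array with standard channels.
zero_epoch_array <- function(n_epochs = 1, n_samples = 512) {
  array(0, c(n_epochs, length(erpdecode:::ALL_CHANNELS), n_samples),
        dimnames = list(NULL, erpdecode:::ALL_CHANNELS, NULL))
}

# Root bipartition of a dendrogram tree as group labels over classes 1..K,
# normalized so class 1 is in group 1.
cutree_partition <- function(tree) {
  K <- length(tree$root$classes)
  g <- integer(K)
  g[tree$root$left$classes] <- 1L
  g[tree$root$right$classes] <- 2L
  if (g[1] == 2L) g <- 3L - g
  g
}

# Normalize an hclust cutree(k = 2) labelling the same way.
sort_split <- function(ct) {
  ct <- as.integer(ct)
  if (ct[1] == 2L) ct <- 3L - ct
  ct
}

# Exhaustive sliding-window peak-to-peak oracle (independent double loop).
p2p_oracle <- function(x, w) {
  n <- length(x)
  if (w >= n) return(diff(range(x)))
  max(vapply(seq_len(n - w + 1), function(i)
    diff(range(x[i:(i + w - 1)])), numeric(1)))
}
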