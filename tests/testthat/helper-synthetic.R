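# Shared synthetic fixtures. Feature extraction is the expensive step, so
# the two-class demo feature table is computed once per test run and cached.

two_class_spec <- function(amp = 0.4, channels = c("L1", "L2", "L3", "L4"),
                           fs = 2000) {
  synthetic_spec(
    fs = fs, duration = 17,
    classes = list(mild = synthetic_class(),
                   severe = synthetic_class(750, amp, channels))
  )
}

.fixture_cache <- new.env(parent = emptyenv())

# 8 recordings per class, 1.5 s segments, EEMD ensemble 20: small enough to
# extract in well under a minute, separated enough to classify cleanly.
demo_feature_table <- function(seed = 1) {
  key <- paste0("tab_", seed)
  if (is.null(.fixture_cache[[key]])) {
    recs <- generate_dataset(two_class_spec(), n_per_class = 8, seed = seed)
    .fixture_cache[[key]] <- extract_dataset(recs, duration_s = 1.5,
                                             ensemble_size = 20, seed = 1)
  }
  .fixture_cache[[key]]
}

# Two well-separated Gaussian blobs in 2-D, for classifier tests.
blob_data <- function(n_per_class = 20, sd = 0.5, seed = 1,
                      center_a = c(0, 0), center_b = c(6, 6)) {
  with_seed <- get("with_seed", asNamespace("copdls"))
  with_seed(seed, {
    x <- rbind(cbind(rnorm(n_per_class, center_a[1], sd),
                     rnorm(n_per_class, center_a[2], sd)),
               cbind(rnorm(n_per_class, center_b[1], sd),
                     rnorm(n_per_class, center_b[2], sd)))
    y <- factor(rep(c("a", "b"), each = n_per_class))
    list(x = x, y = y)
  })
}
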