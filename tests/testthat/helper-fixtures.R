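# shared fixtures, memoised so expensive corpora render once per run
.fixture_env <- new.env(parent = emptyenv())

fixture_corpus <- function(view, n, seed, ...) {
  key <- paste(view, n, seed, paste(unlist(list(...)), collapse = "_"),
               sep = "|")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- phantom_corpus(n, view, seed = seed, ...)
  .fixture_env[[key]]
}

# small disc mask for geometry tests
disc_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2 + 1e-9
}

# brute-force point-to-line distance: minimum Euclidean distance over
# 1e6 points sampled densely along the line through p1, p2
brute_point_line <- function(p, p1, p2, n = 1e6) {
  span <- 2 + 2 * sqrt(sum((p - p1)^2)) / sqrt(sum((p2 - p1)^2))
  t <- seq(-span, span, length.out = n)
  pr <- p1[1] + t * (p2[1] - p1[1])
  pc <- p1[2] + t * (p2[2] - p1[2])
  sqrt(min((pr - p[1])^2 + (pc - p[2])^2))
}
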