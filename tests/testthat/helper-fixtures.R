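# Shared fixtures and independent oracles used across the suite.

# Small, fast stack parameters for unit tests (full-size study conditions are
# exercised in test-acceptance.R).
small_params <- function(seed = 1L, n_nuclei = 12L, n_layers = 6L,
                         width = 384L, ...) {
  stack_params(n_layers = n_layers, width_px = width, height_px = width,
               n_nuclei = n_nuclei, seed = seed, ...)
}

# Draw a binary ellipse mask (semi-axes a, b px) for analytic shape checks.
ellipse_mask <- function(w, h, cx, cy, a, b, theta = 0) {
  m <- matrix(0L, w, h)
  xs <- rep(seq_len(w), h); ys <- rep(seq_len(h), each = w)
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  m[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  m
}

# Independent brute-force oracle for the deduplication step: enumerates every
# partition of the detections into layer-increasing chains whose consecutive
# members are candidate edges, and returns the partition maximising total
# edge SSIM. Chains are canonicalised as "layer:label" strings so partitions
# can be compared as sets.
oracle_best_grouping <- function(detections, edges) {
  n <- length(detections)
  layer <- vapply(detections, `[[`, 0L, "layer")
  label <- vapply(detections, `[[`, 0L, "label")
  ord <- order(layer, label)
  ekey <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) for (r in seq_len(nrow(edges)))
    assign(paste(edges$a[r], edges$b[r]), edges$ssim[r], envir = ekey)
  best <- list(score = -Inf, chains = NULL)
  recurse <- function(pos, chains, lasts, score) {
    if (pos > n) {
      if (score > best$score + 1e-12)
        best <<- list(score = score, chains = chains)
      return(invisible(NULL))
    }
    v <- ord[pos]
    for (ci in seq_along(chains)) {
      w <- ekey[[paste(lasts[ci], v)]]
      if (!is.null(w)) {
        ch <- chains; ch[[ci]] <- c(ch[[ci]], v)
        ls <- lasts; ls[ci] <- v
        recurse(pos + 1L, ch, ls, score + w)
      }
    }
    recurse(pos + 1L, c(chains, list(v)), c(lasts, v), score)
  }
  recurse(1L, list(), integer(0), 0)
  canonical_chains(best$chains, layer, label)
}

canonical_chains <- function(chains, layer, label) {
  sort(vapply(chains, function(ch)
    paste(sprintf("%d:%d", layer[ch], label[ch]), collapse = ","), ""))
}

# Canonical form of the chains implied by a nucleus_records object.
records_chains <- function(records) {
  sort(vapply(attr(records, "members"), function(m)
    paste(sprintf("%d:%d", m$layer, m$label), collapse = ","), ""))
}
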