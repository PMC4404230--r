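# shared fixture builders; everything is generated in code, no files

# minimal map: n markers on one (or more) chromosomes, unit spacing scaled
# to spacing_bp, constant-ish gc unless given
make_map <- function(n, chromosome = "1", spacing_bp = 1000L, gc = NULL) {
  n_total <- n * length(chromosome)
  marker_map(
    marker_id = sprintf("m%04d", seq_len(n_total)),
    chromosome = rep(chromosome, each = n),
    position = rep(seq_len(n) * spacing_bp, length(chromosome)),
    gc = gc %||% rep(0.4, n_total)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# LRR matrix with named rows over a map
make_lrr <- function(samples, map, fill = 0) {
  matrix(fill, length(samples), nrow(map),
         dimnames = list(samples, map$marker_id))
}

# brute-force exact segmentation: enumerate all placements of k-1 cuts and
# return the minimal within-segment RSS (independent of the DP under test)
brute_force_rss <- function(x, k, min_markers = 1L) {
  n <- length(x)
  seg_rss <- function(a, b) {
    v <- x[a:b]
    sum((v - mean(v))^2)
  }
  if (k == 1L) return(seg_rss(1L, n))
  best <- Inf
  for (cuts in utils::combn(seq_len(n - 1L), k - 1L, simplify = FALSE)) {
    bounds <- c(0L, cuts, n)
    lens <- diff(bounds)
    if (any(lens < min_markers)) next
    rss <- sum(vapply(seq_len(k), function(i) {
      seg_rss(bounds[i] + 1L, bounds[i + 1L])
    }, numeric(1)))
    if (rss < best) best <- rss
  }
  best
}

# independent re-implementation of backward cut elimination with the pooled
# t-test (uses stats::t.test, unlike the package's closed form)
oracle_prune <- function(x, cuts, alpha) {
  cuts <- sort(cuts)
  repeat {
    if (length(cuts) == 0L) return(cuts)
    bounds <- c(0L, cuts, length(x))
    p <- sapply(seq_along(cuts), function(i) {
      a <- x[(bounds[i] + 1L):bounds[i + 1L]]
      b <- x[(bounds[i + 1L] + 1L):bounds[i + 2L]]
      stats::t.test(a, b, var.equal = TRUE)$p.value
    })
    worst <- which.max(p)
    if (p[worst] > alpha) cuts <- cuts[-worst] else return(cuts)
  }
}
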