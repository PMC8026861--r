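# Independent oracles, written as direct element-by-element evaluations of
# the defining formulas. They deliberately share no code with the package.

# Fixed/random pooling oracle: explicit loops over studies.
oracle_meta <- function(yi, vi) {
  k <- length(yi)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / vi[i]
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    sw <- sw + w[i]
    swy <- swy + w[i] * yi[i]
    sw2 <- sw2 + w[i]^2
  }
  theta_fixed <- swy / sw
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (yi[i] - theta_fixed)^2
  df <- k - 1
  tau2 <- if (k >= 2) max(0, (Q - df) / (sw - sw2 / sw)) else NA_real_
  if (Q <= df) {
    model <- "fixed"
    isq <- 0
    wm <- w
    tau2_used <- 0
  } else {
    model <- "random"
    isq <- 100 * (Q - df) / Q
    tau2_used <- tau2
    wm <- numeric(k)
    for (i in seq_len(k)) wm[i] <- 1 / (vi[i] + tau2)
  }
  swm <- 0; swmy <- 0
  for (i in seq_len(k)) {
    swm <- swm + wm[i]
    swmy <- swmy + wm[i] * yi[i]
  }
  est <- swmy / swm
  se <- sqrt(1 / swm)
  p <- 2 * stats::pnorm(-abs(est / se))
  list(Q = Q, df = df, tau2 = tau2, tau2_used = tau2_used, est = est,
       se = se, p = p, isq = isq, model = model)
}

# Hypergeometric upper-tail P(X >= overlap) via explicit log-choose summation.
oracle_hyper_tail <- function(overlap, set_size, bg_size, query_size) {
  hi <- min(set_size, query_size)
  if (overlap > hi) return(0)
  terms <- vapply(overlap:hi, function(j) {
    exp(lchoose(set_size, j) + lchoose(bg_size - set_size, query_size - j) -
          lchoose(bg_size, query_size))
  }, numeric(1))
  sum(terms)
}

# Benjamini-Hochberg step-up, coded from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- ranked * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# All minimum-length simple directed paths, via BFS distance + exhaustive DFS.
# Returns a lexicographically sorted list of node-sequence vectors.
oracle_min_paths <- function(edges, source, target) {
  adj <- split(edges$object, edges$subject)
  dist <- stats::setNames(0L, source)
  frontier <- source
  while (length(frontier) > 0 && !(target %in% names(dist))) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (!(u %in% names(dist))) {
          dist[u] <- dist[[v]] + 1L
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (!(target %in% names(dist))) return(list())
  len <- dist[[target]]
  paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == target) {
      if (length(path) - 1L == len) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= len) return(invisible())
    for (u in adj[[v]]) if (!(u %in% path)) dfs(c(path, u))
  }
  dfs(source)
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(keys)]
}

# Protective-network membership by brute-force scan over every gene and
# sign pair, straight off the raw (already aggregated, conflict-free) rows.
oracle_protective <- function(rel, a, b) {
  genes <- unique(c(rel$object[rel$subject == a], rel$subject[rel$object == b]))
  pat <- function(g, pol_a, pol_b) {
    any(rel$subject == a & rel$object == g & rel$polarity == pol_a) &&
      any(rel$subject == g & rel$object == b & rel$polarity == pol_b)
  }
  list(
    inhibited_promoters = sort(Filter(function(g) pat(g, "negative", "positive"), genes)),
    activated_inhibitors = sort(Filter(function(g) pat(g, "positive", "negative"), genes))
  )
}
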