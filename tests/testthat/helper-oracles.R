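# Independent brute-force oracles. Deliberately naive (loops, exhaustive
# enumeration, iterative pruning) and kept free of the package's own code
# paths and of igraph.

# edge lengths for the weighted mode used throughout: f(w) = 1/w
oracle_length_matrix <- function(m, mode) {
  w <- as.matrix(m)
  diag(w) <- 0
  len <- matrix(Inf, nrow(w), ncol(w))
  if (mode == "binary") len[w > 0] <- 1 else len[w > 0] <- 1 / w[w > 0]
  diag(len) <- 0
  len
}

# all-pairs shortest paths by Floyd-Warshall
oracle_shortest_paths <- function(m, mode = "binary") {
  d <- oracle_length_matrix(m, mode)
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# enumerate every simple path between two nodes (tiny graphs only),
# returning a list of node sequences
oracle_all_simple_paths <- function(len, from, to) {
  n <- nrow(len)
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == to) {
      out[[length(out) + 1]] <<- path
      return(invisible(NULL))
    }
    for (nxt in seq_len(n)) {
      if (is.finite(len[cur, nxt]) && nxt != cur && !(nxt %in% path)) {
        walk(c(path, nxt))
      }
    }
  }
  walk(from)
  out
}

# betweenness by exhaustive shortest-path enumeration (ordered pairs,
# normalized by (n-1)(n-2))
oracle_betweenness <- function(m, mode = "binary") {
  len <- oracle_length_matrix(m, mode)
  n <- nrow(len)
  plen <- function(p) sum(len[cbind(p[-length(p)], p[-1])])
  b <- numeric(n)
  for (h in seq_len(n)) {
    for (j in seq_len(n)) {
      if (h == j) next
      paths <- oracle_all_simple_paths(len, h, j)
      if (length(paths) == 0) next
      lens <- vapply(paths, plen, 0)
      mn <- min(lens)
      geo <- paths[abs(lens - mn) < 1e-12]
      for (i in seq_len(n)) {
        if (i == h || i == j) next
        thru <- sum(vapply(geo, function(p) i %in% p, TRUE))
        b[i] <- b[i] + thru / length(geo)
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

oracle_clustering_bin <- function(a) {
  a <- (as.matrix(a) > 0) * 1
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (j in nb) for (h in nb) if (j != h && a[j, h] > 0) tri <- tri + 1
    out[i] <- tri / (k * (k - 1))
  }
  out
}

oracle_clustering_wei <- function(w) {
  w <- as.matrix(w)
  diag(w) <- 0
  wn <- if (max(w) > 0) w / max(w) else w
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || h == j) next
        s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_closeness <- function(m, mode = "binary") {
  w <- as.matrix(m)
  diag(w) <- 0
  a <- (w > 0) * 1
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    dsub <- oracle_shortest_paths(sub, mode)
    s <- 0
    for (jj in seq_len(k)) {
      for (hh in seq_len(k)) {
        if (jj == hh) next
        din <- if (is.finite(dsub[jj, hh])) 1 / dsub[jj, hh] else 0
        s <- s + if (mode == "binary") din else
          (w[i, nb[jj]] * w[i, nb[hh]] * din)^(1 / 3)
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_char_path_length <- function(m, mode = "binary") {
  d <- oracle_shortest_paths(m, mode)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_transitivity <- function(m, mode = "binary") {
  w <- as.matrix(m)
  diag(w) <- 0
  a <- (w > 0) * 1
  wn <- if (mode == "weighted" && max(w) > 0) w / max(w) else a
  n <- nrow(w)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    den <- den + k * (k - 1)
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || h == j) next
        num <- num + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
    }
  }
  if (den == 0) 0 else num / den
}

# assortativity via the doubled edge list (each edge appears with both
# endpoint orders), plain population moments
oracle_assortativity <- function(m, mode = "binary") {
  w <- as.matrix(m)
  diag(w) <- 0
  a <- (w > 0) * 1
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  l <- nrow(idx)
  if (mode == "binary") {
    k <- rowSums(a)
    wij <- rep(1, 2 * l)
  } else {
    k <- rowSums(w)
    wij <- c(w[idx], w[idx])
  }
  x <- c(k[idx[, 1]], k[idx[, 2]])
  y <- c(k[idx[, 2]], k[idx[, 1]])
  mu <- sum(wij * x) / (2 * l)
  num <- sum(wij * x * y) / (2 * l) - mu^2
  den <- sum(wij * x^2) / (2 * l) - mu^2
  num / den
}

# rich-club curve by naive re-count: strip nodes with degree <= k, count
# surviving edges
oracle_phi <- function(a) {
  a <- (as.matrix(a) > 0) * 1
  deg <- rowSums(a)
  res <- list()
  for (k in 0:(max(deg) - 1)) {
    keep <- which(deg > k)
    if (length(keep) < 2) next
    e <- 0
    for (i in keep) for (j in keep) if (j > i && a[i, j] > 0) e <- e + 1
    res[[length(res) + 1]] <- c(k = k,
                                phi = 2 * e / (length(keep) * (length(keep) - 1)))
  }
  do.call(rbind, res)
}

# k-core by iterative pruning
oracle_kcore <- function(a, k) {
  a <- (as.matrix(a) > 0) * 1
  alive <- rep(TRUE, nrow(a))
  repeat {
    deg <- rowSums(a[, alive, drop = FALSE])
    drop <- alive & deg < k
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  alive
}

# modularity by explicit double loop
oracle_q <- function(m, memb, gamma_res = 1) {
  w <- as.matrix(m)
  diag(w) <- 0
  k <- rowSums(w)
  two_m <- sum(w)
  n <- nrow(w)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + w[i, j] - gamma_res * k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}
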