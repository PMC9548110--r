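# Independent oracles and graph fixtures shared across test files. Each
# oracle is a deliberately naive re-derivation (set arithmetic, exhaustive
# enumeration, brute force) kept free of the code paths it checks.

make_wgraph <- function(...) {
  # make_wgraph("a","b",1, "b","c",2, ...)
  x <- list(...)
  stopifnot(length(x) %% 3 == 0)
  idx <- seq(1, length(x), by = 3)
  weighted_graph(data.frame(
    from = as.character(unlist(x[idx])),
    to = as.character(unlist(x[idx + 1])),
    weight = as.numeric(unlist(x[idx + 2])),
    stringsAsFactors = FALSE))
}

random_binary_gpa <- function(n_genomes, n_genes, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_genomes * n_genes, 1, p), n_genomes, n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genomes)),
                                sprintf("f%03d", seq_len(n_genes))))
    if (all(colSums(m) > 0)) return(gpa_matrix(m))
  }
}

random_weighted_graph <- function(n, p = 0.4, seed = 1,
                                  weights = function(m) runif(m, 0.1, 1)) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      weight = weights(sum(keep)),
                      stringsAsFactors = FALSE)
  weighted_graph(edges, nodes = nodes)
}

# --- similarity oracle: per-pair set arithmetic --------------------------
oracle_similarity <- function(values, metric) {
  n <- nrow(values)
  out <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      si <- which(values[i, ] == 1)
      sj <- which(values[j, ] == 1)
      inter <- length(intersect(si, sj))
      uni <- length(union(si, sj))
      out[i, j] <- switch(metric,
        jaccard = if (uni == 0) 0 else inter / uni,
        cosine = if (length(si) == 0 || length(sj) == 0) 0 else
          inter / sqrt(length(si) * length(sj)),
        euclidean_sim = 1 / (1 + sqrt(sum((values[i, ] - values[j, ])^2))))
    }
  }
  out
}

# --- k-NN oracle: materialise every node's sorted edge list --------------
oracle_knn_edges <- function(g, k, mutual = FALSE) {
  nodes <- igraph::V(g)$name
  et <- graph_edge_table(g)
  et$id <- seq_len(nrow(et))
  topk <- lapply(nodes, function(v) {
    inc <- et[et$from == v | et$to == v, ]
    if (!nrow(inc)) return(integer(0))
    partner <- ifelse(inc$from == v, inc$to, inc$from)
    inc <- inc[order(-inc$weight, partner), ]
    inc$id[seq_len(min(k, nrow(inc)))]
  })
  ids <- if (mutual) {
    tab <- table(unlist(topk))
    as.integer(names(tab)[tab == 2])
  } else {
    sort(unique(unlist(topk)))
  }
  et[et$id %in% ids, c("from", "to", "weight")]
}

# --- Fisher oracle: factorial-arithmetic enumeration ---------------------
# independent of dhyper(): table probabilities from lchoose sums.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(k) {
    lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)
  }, numeric(1))
  p <- exp(lp)
  p_obs <- p[a - lo + 1]
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# --- partition enumeration (restricted growth strings) -------------------
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# weighted modularity at resolution gamma, from the definition
oracle_modularity <- function(g, membership, gamma = 1) {
  et <- graph_edge_table(g)
  nodes <- igraph::V(g)$name
  m2 <- 2 * sum(et$weight)
  if (m2 == 0) return(0)
  strength <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(et))) {
    strength[et$from[i]] <- strength[et$from[i]] + et$weight[i]
    strength[et$to[i]] <- strength[et$to[i]] + et$weight[i]
  }
  q <- 0
  for (cl in unique(membership)) {
    inside <- nodes[membership == cl]
    w_in <- sum(et$weight[et$from %in% inside & et$to %in% inside])
    q <- q + w_in / (m2 / 2) - gamma * (sum(strength[inside]) / m2)^2
  }
  q
}

max_modularity_partition <- function(g, gamma = 1) {
  nodes <- igraph::V(g)$name
  parts <- enumerate_partitions(length(nodes))
  best <- -Inf
  best_p <- NULL
  for (p in parts) {
    q <- oracle_modularity(g, setNames(p, nodes), gamma)
    if (q > best + 1e-12) {
      best <- q
      best_p <- setNames(p, nodes)
    }
  }
  list(q = best, membership = best_p)
}

# --- MCL reference oracle (independent numpy implementation) -------------
oracle_mcl <- function(g, inflation) {
  script <- system.file("oracle", "mcl_oracle.py", package = "pangenet")
  stopifnot(nzchar(script))
  et <- graph_edge_table(g)
  iso <- setdiff(igraph::V(g)$name, unique(c(et$from, et$to)))
  infile <- tempfile()
  writeLines(sprintf("%s %s %.17g", et$from, et$to, et$weight), infile)
  out <- system2("python", c(script, format(inflation)), stdin = infile,
                 stdout = TRUE)
  clusters <- strsplit(out, "\t", fixed = TRUE)
  clusters <- c(clusters, as.list(iso))          # isolated nodes: singletons
  labels <- unlist(lapply(seq_along(clusters), function(i)
    setNames(rep(i, length(clusters[[i]])), clusters[[i]])))
  labels
}

# do two labelled partitions describe the same grouping?
same_partition <- function(a, b) {
  ids <- sort(names(a))
  if (!setequal(ids, names(b))) return(FALSE)
  ka <- split(ids, unname(a[ids]))
  kb <- split(ids, unname(b[ids]))
  setequal(lapply(ka, sort), lapply(kb, sort))
}
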