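# Independent brute-force oracles, kept free of the implementations they check.

# AUC by explicit enumeration of all positive x negative pairs (ties = 1/2)
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(sp) * length(sn))
}

# centralities from first principles on an adjacency matrix:
# BFS distances, level-DP shortest-path counts, pair-summed betweenness
brute_centralities <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n) # number of shortest paths s -> t
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nbrs <- which(apply(adj[frontier, , drop = FALSE] > 0, 2, any))
      nbrs <- nbrs[is.infinite(dist[nbrs])]
      if (!length(nbrs)) break
      dist[nbrs] <- dist[frontier[1]] + 1
      frontier <- nbrs
    }
    D[s, ] <- dist
    cnt <- rep(0, n)
    cnt[s] <- 1
    for (d in sort(unique(dist[is.finite(dist) & dist > 0]))) {
      for (v in which(dist == d)) {
        pred <- which(adj[, v] > 0 & dist == d - 1)
        cnt[v] <- sum(cnt[pred])
      }
    }
    sigma[s, ] <- cnt
  }

  DC <- rowSums(adj) / (n - 1)

  CCo <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))

  CC <- vapply(seq_len(n), function(v) {
    members <- which(is.finite(D[v, ]))
    csize <- length(members)
    if (csize == 1) return(0)
    S <- sum(D[v, members])
    ((csize - 1) / S) * ((csize - 1) / (n - 1))
  }, numeric(1))

  BC <- numeric(n)
  for (v in seq_len(n)) {
    total <- 0
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
      if (s == v || t == v || !is.finite(D[s, t]) || sigma[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        total <- total + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    BC[v] <- total
  }
  if (n > 2) BC <- BC / ((n - 1) * (n - 2) / 2)

  data.frame(DC = DC, CCo = CCo, CC = CC, BC = BC)
}

# closed-form Pearson correlation (textbook covariance / sd ratio)
closed_form_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}
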