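# Independent brute-force oracles for the graph attributes, written against
# the definitions only (no shared code with the package internals).

# boolean transitive closure by repeated matrix "multiplication"
oracle_reach <- function(adj) {
  n <- nrow(adj)
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

oracle_adj <- function(tokens) {
  nodes <- unique(tokens)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(tokens) > 1)
    for (i in seq_len(length(tokens) - 1))
      adj[tokens[i], tokens[i + 1]] <- TRUE
  adj
}

# largest SCC: u, v in the same component iff u reaches v and v reaches u
oracle_lsc <- function(tokens) {
  adj <- oracle_adj(tokens)
  n <- nrow(adj)
  if (n == 1) return(1L)
  reach <- oracle_reach(adj)
  mutual <- (reach & t(reach)) | diag(TRUE, n)
  max(vapply(seq_len(n), function(u) sum(mutual[u, ] & mutual[, u]),
             integer(1)))
}

# mean shortest directed path over reachable ordered pairs u != v,
# by exhaustive breadth-first search
oracle_asp <- function(tokens) {
  adj <- oracle_adj(tokens)
  n <- nrow(adj)
  total <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- integer()
      for (u in frontier)
        for (v in which(adj[u, ]))
          if (is.na(dist[v])) {
            dist[v] <- d
            nxt <- c(nxt, v)
          }
      frontier <- nxt
    }
    ok <- !is.na(dist) & seq_len(n) != s
    total <- total + sum(dist[ok])
    pairs <- pairs + sum(ok)
  }
  if (pairs == 0) 0 else total / pairs
}

rand_tokens <- function(len, vocab = 5) {
  sample(letters[seq_len(vocab)], len, replace = TRUE)
}
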