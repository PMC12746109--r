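# Independent brute-force oracles used to verify the implementation.
# These deliberately use naive algorithms and stay independent of the
# package's code paths.

# --- span matching: enumerate ALL one-to-one pred->gold matchings and
# maximise the mode's credit (strict: exact matches only; partial: 1 per
# exact + 0.5 per overlapping non-exact match).
oracle_match <- function(pred, gold, mode) {
  np <- nrow(pred); ng <- nrow(gold)
  if (!np || !ng) return(list(cor = 0L, par = 0L))
  best <- c(-1, 0, 0) # credit, cor, par
  recurse <- function(i, used, cor, par) {
    if (i > np) {
      credit <- if (mode == "strict") cor else cor + 0.5 * par
      if (credit > best[1] + 1e-12 ||
          (abs(credit - best[1]) <= 1e-12 && cor > best[2])) {
        best <<- c(credit, cor, par)
      }
      return(invisible())
    }
    recurse(i + 1L, used, cor, par) # unmatched
    for (j in seq_len(ng)) {
      if (used[j]) next
      ov <- min(pred$end[i], gold$end[j]) - max(pred$start[i], gold$start[j])
      if (ov <= 0) next
      exact <- pred$start[i] == gold$start[j] && pred$end[i] == gold$end[j]
      if (mode == "strict" && !exact) next
      used[j] <- TRUE
      recurse(i + 1L, used, cor + as.integer(exact),
              par + as.integer(!exact))
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ng), 0L, 0L)
  list(cor = as.integer(best[2]), par = as.integer(best[3]))
}

oracle_ner_metrics <- function(pred, gold, mode) {
  cor <- 0L; par <- 0L; np <- 0L; ng <- 0L
  for (i in seq_along(pred)) {
    m <- oracle_match(pred[[i]], gold[[i]], mode)
    cor <- cor + m$cor; par <- par + m$par
    np <- np + nrow(pred[[i]]); ng <- ng + nrow(gold[[i]])
  }
  credit <- if (mode == "strict") cor else cor + 0.5 * par
  P <- if (np) credit / np else 0
  R <- if (ng) credit / ng else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(COR = cor, PAR = par, P = P, R = R, F1 = F1)
}

# random per-sentence span sets (disjoint within a side) on a small token grid
random_span_set <- function(max_spans = 4L, grid = 12L) {
  n <- sample.int(max_spans + 1L, 1L) - 1L
  if (!n) return(data.frame(start = integer(), end = integer()))
  bounds <- sort(sample.int(grid, 2L * n))
  data.frame(start = bounds[seq(1, 2 * n, 2)] - 1L,
             end = bounds[seq(2, 2 * n, 2)])
}

# --- naive betweenness by all-pairs shortest-path enumeration (BFS counts)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s, counting shortest paths
    dist <- rep(Inf, n); sigma <- numeric(n); preds <- vector("list", n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
      frontier <- unique(nxt)
    }
    # accumulate dependency in decreasing-distance order
    delta <- numeric(n)
    for (w in order(dist, decreasing = TRUE)) {
      if (is.infinite(dist[w]) || w == s) next
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
    }
    btw <- btw + ifelse(seq_len(n) == s, 0, delta)
  }
  btw
}

# --- brute-force triad enumeration over all (s_i, compound, s_j) triples
oracle_triads <- function(sub) {
  e <- unique(sub$edges[, c("source", "target", "type")])
  has <- function(a, b, type) {
    any(e$source == a & e$target == b & e$type == type)
  }
  strains <- sub$strains
  comps <- unique(c(e$target[e$type != "INHIBITS"],
                    e$source[e$type == "INHIBITS"]))
  rows <- list()
  for (si in strains) for (sj in strains) for (comp in comps) {
    if (si == sj) next
    if (si < sj && has(si, comp, "DEGRADES") && has(sj, comp, "DEGRADES")) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "competition", strain_i = si, strain_j = sj,
        compound = comp, sign = -1L)
    }
    if (has(si, comp, "PRODUCES") && has(comp, sj, "INHIBITS")) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "direct_inhibition", strain_i = si, strain_j = sj,
        compound = comp, sign = -1L)
    }
    if (has(si, comp, "PRODUCES") && has(sj, comp, "DEGRADES")) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "cross_feeding", strain_i = si, strain_j = sj,
        compound = comp, sign = +1L)
    }
    if (has(si, comp, "PRODUCES") && has(sj, comp, "RESISTS")) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "resistance", strain_i = si, strain_j = sj,
        compound = comp, sign = +1L)
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), strain_i = character(),
                      strain_j = character(), compound = character(),
                      sign = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$type, out$strain_i, out$strain_j, out$compound), ,
      drop = FALSE]
}

# --- grid-search maximiser of the discrete power-law log-likelihood.
# Independent of the package's optimiser: plain grid search, with the zeta
# normalization by direct summation plus a standard integral tail bound.
# Two-stage grid (coarse 0.01, then 1e-4 around the coarse maximum).
oracle_zeta <- function(a, q, kmax = 1e5) {
  k <- q:kmax
  sum(k^(-a)) + (kmax + 0.5)^(1 - a) / (a - 1)
}
oracle_pl_grid_pass <- function(x, xmin, grid) {
  slx <- sum(log(x)); n <- length(x)
  ll <- vapply(grid, function(a) -a * slx - n * log(oracle_zeta(a, xmin)),
               numeric(1))
  grid[which.max(ll)]
}
oracle_pl_alpha_grid <- function(x, xmin, lo = 1.2, hi = 6, step = 1e-4) {
  coarse <- oracle_pl_grid_pass(x, xmin, seq(lo, hi, by = 0.01))
  oracle_pl_grid_pass(x, xmin,
                      seq(max(lo, coarse - 0.02), min(hi, coarse + 0.02),
                          by = step))
}

# --- two-sided Fisher exact p by direct hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n_ <- c_ + d; k <- a + c_
  support <- max(0, k - n_):min(k, m)
  probs <- vapply(support, function(x)
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)),
    numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- textbook Levenshtein DP (full), and substring (partial) distance by
# minimising over all substrings of the longer string
oracle_lev <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  D <- matrix(0L, na + 1L, nb + 1L)
  D[, 1] <- 0:na; D[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                           D[i, j] + (ca[i] != cb[j]))
  }
  D[na + 1, nb + 1]
}
oracle_partial_lev <- function(pattern, text) {
  nt <- nchar(text)
  best <- nchar(pattern)
  for (i in seq_len(nt + 1L) - 1L) for (j in i:nt) {
    sub <- substr(text, i + 1L, j)
    best <- min(best, oracle_lev(pattern, sub))
  }
  best
}

# --- BH adjustment reference (textbook step-up, independent of p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    i <- ord[r]
    prev <- min(prev, p[i] * m / r)
    q[i] <- prev
  }
  q
}
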