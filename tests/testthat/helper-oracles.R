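# Independent oracles and small fixture builders used across the suite.

toy_genomes <- function(seqs, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  genome_set(seqs, genome_id = ids, seq_id = rep("c1", length(seqs)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force de Bruijn edge enumeration: all (k+1)-mer occurrences of a
# set of strings, splitting at non-ACGT characters.
oracle_edges <- function(seqs, k) {
  out <- list()
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    ok <- chars %in% c("A", "C", "G", "T")
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      a <- starts[i]; bnd <- ends[i]
      if (bnd - a + 1L < k + 1L) next
      for (off in a:(bnd - k)) {
        if (off + k <= bnd) out[[length(out) + 1L]] <- substr(s, off, off + k)
      }
    }
  }
  unlist(out) %||% character(0)
}

# Brute-force k-mer (vertex) enumeration.
oracle_vertices <- function(seqs, k) {
  unique(oracle_edges(seqs, k - 1L))
}

# Exhaustive chain decomposition: maximal q2 over all subpath/subwalk
# pairs and all bubble tilings; ties resolved towards minimal q1.
oracle_decompose <- function(pa, p, b) {
  V <- pa$vertices; U <- p$vertices
  cum <- c(0, cumsum(pa$lengths)); pcv <- c(0, cumsum(p$lengths))
  N <- length(V); M <- length(U)
  bubble_ok <- function(i, s, j, t) {
    if (cum[j] - cum[i] > b || cum[j] - cum[i] < 1) return(FALSE)
    if (pcv[t] - pcv[s] > b || pcv[t] - pcv[s] < 1) return(FALSE)
    VS <- V[i:j]; US <- U[s:t]
    iV <- if (j - i > 1) V[(i + 1):(j - 1)] else character(0)
    iU <- if (t - s > 1) U[(s + 1):(t - 1)] else character(0)
    !any(iV %in% US) && !any(iU %in% VS)
  }
  memo <- new.env(parent = emptyenv())
  can_tile <- function(i, s, j, t) {
    key <- paste(i, s, j, t)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- FALSE
    if (bubble_ok(i, s, j, t)) res <- TRUE
    if (!res) {
      for (h in (i + 1):j) {
        if (h >= j) break
        for (u in (s + 1):t) {
          if (u >= t) break
          if (V[h] == U[u] && bubble_ok(i, s, h, u) && can_tile(h, u, j, t)) {
            res <- TRUE; break
          }
        }
        if (res) break
      }
    }
    memo[[key]] <- res
    res
  }
  best <- c(q1 = 0, q2 = 0, q3 = cum[N])
  for (i in seq_len(N)) for (s in seq_len(M)) {
    if (V[i] != U[s]) next
    for (j in seq_len(N)) for (t in seq_len(M)) {
      if (j <= i || t <= s || V[j] != U[t]) next
      if (!can_tile(i, s, j, t)) next
      q2 <- cum[j] - cum[i]; q1 <- cum[i]
      if (q2 > best["q2"] || (q2 == best["q2"] && q1 < best["q1"])) {
        best <- c(q1 = q1, q2 = q2, q3 = cum[N] - cum[j])
      }
    }
  }
  best
}

# Plain O(nm) edit-distance DP (unit costs), small inputs only.
oracle_edit <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j] + (ca[i] != cb[j]),
                             d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
  }
  d[n + 1L, m + 1L]
}

# Random tangled sequence over a reduced alphabet (forces repeats).
rand_seq <- function(len, alpha = 2L) {
  paste(sample(c("A", "C", "G", "T")[seq_len(alpha)], len, replace = TRUE),
        collapse = "")
}

# Longest prefix of a contig walk with pairwise distinct vertices (a
# valid carrying path).
path_prefix <- function(w) {
  keep <- !duplicated(w$vertices)
  n <- which(!keep)[1]
  if (is.na(n)) return(w)
  if (n <= 2L) return(NULL)
  vertex_walk(w$vertices[seq_len(n - 1L)], w$lengths[seq_len(n - 2L)])
}

# Column-pair enumeration oracle for relation_from_maf.
oracle_relation_pairs <- function(ab) {
  mat <- do.call(rbind, strsplit(ab$text, "", fixed = TRUE))
  keys <- character(0)
  for (col in seq_len(ncol(mat))) {
    rows <- which(mat[, col] != "-")
    if (length(rows) < 2L) next
    for (ii in seq_len(length(rows) - 1L)) for (jj in (ii + 1L):length(rows)) {
      r1 <- rows[ii]; r2 <- rows[jj]
      posof <- function(r) {
        jns <- sum(mat[r, seq_len(col)] != "-") - 1L
        if (ab$occ$strand[r] == "+") ab$occ$start[r] + jns else ab$occ$end[r] - 1L - jns
      }
      k1 <- paste(ab$occ$genome_id[r1], ab$occ$seq_id[r1], posof(r1))
      k2 <- paste(ab$occ$genome_id[r2], ab$occ$seq_id[r2], posof(r2))
      fl <- ab$occ$strand[r1] != ab$occ$strand[r2]
      keys <- c(keys, paste(min(k1, k2), max(k1, k2), fl))
    }
  }
  sort(unique(keys))
}
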