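# Greedy seed-and-extend reconstruction of collinear blocks.
#
# Each distinct compacted-edge class is tried as a seed. A seed
# initialises a carrying path with the seed edge and one single-edge
# collinear walk per unused parallel occurrence. Phases then extend the
# carrying path by the genomic walk that the b-extensions of the current
# walks visit most often, walks are extended to keep forming chains with
# the carrying path, and the highest-scoring intermediate state is
# remembered. Extension stops when the collinearity score goes negative;
# the best state is then extended symmetrically to the left. Accepted
# blocks mark their edges (and reverse-complement twins) as used.
#
# The engine keeps per-walk incremental chain state (the active chain run
# against the carrying path plus the best closed run); when a block is
# accepted, every reported walk's split is recomputed with the exact
# chain decomposition and the block score re-derived from it.

# ---- engine construction ---------------------------------------------------

lcb_engine <- function(cg, used = NULL) {
  nE <- nrow(cg$edges)
  nV <- length(cg$vertices)
  no <- nrow(cg$oseq)
  oe <- vector("list", no); oc <- vector("list", no); of <- vector("list", no)
  for (o in seq_len(no)) {
    key <- as.character(o)
    oe[[o]] <- cg$o_eids[[key]] %||% integer(0)
    oc[[o]] <- cg$o_cum[[key]] %||% 0
    of[[o]] <- cg$o_frag[[key]] %||% integer(0)
  }
  env <- new.env(parent = emptyenv())
  env$cg <- cg
  env$e_oseq <- cg$edges$oseq; env$e_idx <- cg$edges$idx
  env$e_u <- cg$edges$u; env$e_v <- cg$edges$v
  env$e_len <- cg$edges$len; env$e_twin <- cg$edges$twin
  env$e_sp <- cg$edges$spelled
  env$e_rank <- cg$edges$rank; env$e_dir <- cg$edges$dir
  env$oe <- oe; env$oc <- oc; env$of <- of
  env$in_map <- cg$in_map
  env$used <- used %||% logical(nE)
  env$claim_ser <- integer(nE); env$ser_c <- 0L
  env$vis_ser <- integer(nV); env$vis_idx <- integer(nV); env$ser_v <- 0L
  env$tmin <- rep(Inf, no); env$tmax <- rep(-Inf, no)
  env
}

touch_range <- function(env, o, i1, i2) {
  if (i1 < env$tmin[o]) env$tmin[o] <- i1
  if (i2 > env$tmax[o]) env$tmax[o] <- i2
  invisible(NULL)
}

claim_edges <- function(env, eids) {
  env$claim_ser[eids] <- env$ser_c
  tw <- env$e_twin[eids]
  tw <- tw[!is.na(tw)]
  if (length(tw)) env$claim_ser[tw] <- env$ser_c
  invisible(NULL)
}

unclaim_edges <- function(env, eids) {
  env$claim_ser[eids] <- 0L
  tw <- env$e_twin[eids]
  tw <- tw[!is.na(tw)]
  if (length(tw)) env$claim_ser[tw] <- 0L
  invisible(NULL)
}

# ---- per-seed state --------------------------------------------------------

seed_state <- function(env) {
  st <- new.env(parent = emptyenv())
  st$pa_n <- 0L
  st$pa_v <- integer(256L); st$pa_cum <- numeric(256L)
  st$pa_lab <- character(256L)
  st$nW <- 0L
  cap <- 64L
  st$W_o <- integer(cap); st$W_i1 <- integer(cap); st$W_i2 <- integer(cap)
  st$W_len <- numeric(cap); st$W_endv <- integer(cap)
  st$W_as <- integer(cap); st$W_ae <- integer(cap); st$W_aep <- numeric(cap)
  st$W_bs <- integer(cap); st$W_be <- integer(cap)
  st$snap <- NULL
  st
}

grow_walks <- function(st) {
  cap <- length(st$W_o)
  for (f in c("W_o", "W_i1", "W_i2", "W_endv", "W_as", "W_ae", "W_bs", "W_be")) {
    st[[f]] <- c(st[[f]], integer(cap))
  }
  st$W_len <- c(st$W_len, numeric(cap))
  st$W_aep <- c(st$W_aep, numeric(cap))
}

pa_append <- function(env, st, vid, len, lab = "") {
  n <- st$pa_n + 1L
  if (n > length(st$pa_v)) {
    st$pa_v <- c(st$pa_v, integer(length(st$pa_v)))
    st$pa_cum <- c(st$pa_cum, numeric(length(st$pa_cum)))
    st$pa_lab <- c(st$pa_lab, character(length(st$pa_lab)))
  }
  st$pa_v[n] <- vid
  st$pa_cum[n] <- if (n == 1L) 0 else st$pa_cum[n - 1L] + len
  if (n > 1L) st$pa_lab[n - 1L] <- lab
  st$pa_n <- n
  env$vis_ser[vid] <- env$ser_v
  env$vis_idx[vid] <- n
  n
}

# Incremental chain scan of walk `w` over its edge range `rng` (indices
# into its oriented sequence). Closes a bubble at every carrying-path
# vertex met in order within the b-windows; on an out-of-order or
# over-long match the active run is promoted to the best closed run and
# a new run starts at the match.
scan_chain <- function(env, st, w, rng, reset) {
  o <- st$W_o[w]
  ids <- env$oe[[o]][rng]
  if (reset) {
    pc <- 0
    e1 <- ids[1L]
    u0 <- env$e_u[e1]
    st$W_bs[w] <- 0L; st$W_be[w] <- 0L
    if (env$vis_ser[u0] == env$ser_v) {
      h <- env$vis_idx[u0]
      st$W_as[w] <- h; st$W_ae[w] <- h; st$W_aep[w] <- 0
    } else {
      st$W_as[w] <- 0L; st$W_ae[w] <- 0L; st$W_aep[w] <- 0
    }
  } else {
    pc <- st$W_len[w]
  }
  b <- st$b
  as <- st$W_as[w]; ae <- st$W_ae[w]; aep <- st$W_aep[w]
  bs <- st$W_bs[w]; be <- st$W_be[w]
  pa_cum <- st$pa_cum
  for (t in seq_along(ids)) {
    e <- ids[t]
    pc <- pc + env$e_len[e]
    z <- env$e_v[e]
    if (env$vis_ser[z] != env$ser_v) next
    h <- env$vis_idx[z]
    if (ae == 0L) { as <- h; ae <- h; aep <- pc; next }
    # two parallel compacted edges always chain (a run of unit bubbles)
    prl <- h == ae + 1L && pc - env$e_len[e] == aep &&
      env$e_sp[e] == st$pa_lab[ae]
    if (h > ae && (prl || (pa_cum[h] - pa_cum[ae] <= b && pc - aep <= b))) {
      ae <- h; aep <- pc            # bubble closed: chain lengthened
    } else if (h >= ae) {
      # chain broken (over-long gap, or the walk revisits the chain end):
      # promote the active run if it holds a bubble, restart at the match
      if (ae > as) {
        cb <- if (bs > 0L) pa_cum[be] - pa_cum[bs] else -1
        ca <- pa_cum[ae] - pa_cum[as]
        if (ca > cb || (ca == cb && bs > 0L && pa_cum[as] < pa_cum[bs])) {
          bs <- as; be <- ae
        }
      }
      as <- h; ae <- h; aep <- pc
    }
    # h < ae: backward match; it lies outside future carrying-path
    # segments, so it neither extends nor invalidates the chain
  }
  st$W_as[w] <- as; st$W_ae[w] <- ae; st$W_aep[w] <- aep
  st$W_bs[w] <- bs; st$W_be[w] <- be
  invisible(NULL)
}

walk_create <- function(env, st, x) {
  st$nW <- st$nW + 1L
  if (st$nW > length(st$W_o)) grow_walks(st)
  w <- st$nW
  o <- env$e_oseq[x]; ix <- env$e_idx[x]
  st$W_o[w] <- o; st$W_i1[w] <- ix; st$W_i2[w] <- ix
  st$W_len[w] <- 0
  st$W_endv[w] <- env$e_v[x]
  claim_edges(env, x)
  touch_range(env, o, ix, ix)
  scan_chain(env, st, w, ix, reset = TRUE)
  st$W_len[w] <- env$e_len[x]
  w
}

walk_extend <- function(env, st, w, ix) {
  o <- st$W_o[w]
  rng <- (st$W_i2[w] + 1L):ix
  claim_edges(env, env$oe[[o]][rng])
  touch_range(env, o, rng[1L], ix)
  scan_chain(env, st, w, rng, reset = FALSE)
  st$W_len[w] <- st$W_len[w] + sum(env$e_len[env$oe[[o]][rng]])
  st$W_i2[w] <- ix
  st$W_endv[w] <- env$e_v[env$oe[[o]][ix]]
  invisible(NULL)
}

# Replay the chain state of walk w from scratch (used after truncation
# or reversal).
walk_replay <- function(env, st, w) {
  o <- st$W_o[w]
  rng <- st$W_i1[w]:st$W_i2[w]
  st$W_len[w] <- 0
  scan_chain(env, st, w, rng, reset = TRUE)
  st$W_len[w] <- sum(env$e_len[env$oe[[o]][rng]])
  st$W_endv[w] <- env$e_v[env$oe[[o]][st$W_i2[w]]]
  invisible(NULL)
}

# Vectorised per-walk scores against the current carrying path.
score_walks <- function(st, m, b) {
  n <- st$nW
  if (n == 0L) return(numeric(0))
  idx <- seq_len(n)
  pa_cum <- st$pa_cum
  CN <- if (st$pa_n > 0L) pa_cum[st$pa_n] else 0
  lenv <- st$W_len[idx]
  as <- st$W_as[idx]; ae <- st$W_ae[idx]
  bs <- st$W_bs[idx]; be <- st$W_be[idx]
  ca <- ifelse(ae > as & as > 0L, pa_cum[pmax(ae, 1L)] - pa_cum[pmax(as, 1L)], 0)
  cb <- ifelse(bs > 0L, pa_cum[pmax(be, 1L)] - pa_cum[pmax(bs, 1L)], 0)
  use_act <- ca > cb | (ca == cb & ca > 0 &
                          (bs == 0L | pa_cum[pmax(as, 1L)] < pa_cum[pmax(bs, 1L)]))
  cs <- ifelse(use_act, ca, cb)
  s_idx <- ifelse(use_act, as, bs)
  e_idx <- ifelse(use_act, ae, be)
  q1 <- ifelse(cs > 0, pa_cum[pmax(s_idx, 1L)], 0)
  q3 <- ifelse(cs > 0, CN - pa_cum[pmax(e_idx, 1L)], CN)
  ifelse(lenv < m, 0, ifelse(q1 > b | q3 > b, -Inf, lenv - (q1 + q3)^2))
}

# Walk update: extend the collinear walks after vertex `vid` (carrying-path
# index i) has been appended.
update_walks <- function(env, st, vid) {
  xs <- env$in_map[[vid]]
  if (is.null(xs)) return(invisible(NULL))
  b <- st$b
  for (x in xs) {
    if (env$used[x] || env$claim_ser[x] == env$ser_c) next
    o <- env$e_oseq[x]; ix <- env$e_idx[x]
    touch_range(env, o, max(1L, ix - 1L), ix)
    n <- st$nW
    best_w <- 0L; best_i2 <- 0L
    if (n > 0L) {
      sel <- which(st$W_o[seq_len(n)] == o & st$W_i2[seq_len(n)] < ix)
      if (length(sel)) {
        wi <- sel[which.max(st$W_i2[sel])]
        best_w <- wi; best_i2 <- st$W_i2[wi]
      }
    }
    extended <- FALSE
    if (best_w > 0L) {
      ofr <- env$of[[o]]; ocum <- env$oc[[o]]
      if (ofr[best_i2] == ofr[ix] &&
          (ix == best_i2 + 1L || ocum[ix + 1L] - ocum[best_i2 + 1L] <= b)) {
        rng <- (best_i2 + 1L):ix
        sub <- env$oe[[o]][rng]
        touch_range(env, o, rng[1L], ix)
        if (!any(env$used[sub]) && !any(env$claim_ser[sub] == env$ser_c)) {
          walk_extend(env, st, best_w, ix)
          extended <- TRUE
        }
      }
    }
    if (!extended) walk_create(env, st, x)
  }
  invisible(NULL)
}

# b-extension edge-index range of walk w (empty integer() if none);
# truncated at the fragment end and before the first used edge.
ext_range <- function(env, st, w, b) {
  o <- st$W_o[w]
  ids <- env$oe[[o]]; ofr <- env$of[[o]]; ocum <- env$oc[[o]]
  n <- length(ids)
  i <- st$W_i2[w] + 1L
  if (i > n || ofr[i] != ofr[st$W_i2[w]] || env$used[ids[i]]) {
    if (i <= n) touch_range(env, o, i, i)
    return(integer(0))
  }
  j <- i
  while (j + 1L <= n && ofr[j + 1L] == ofr[i] && ocum[j + 2L] - ocum[i] <= b &&
         !env$used[ids[j + 1L]]) {
    j <- j + 1L
  }
  touch_range(env, o, i, min(n, j + 1L))
  i:j
}

# Pick the extension target and the walk that carries the path there.
choose_extension <- function(env, st, b) {
  n <- st$nW
  if (n == 0L || st$pa_n == 0L) return(NULL)
  w0 <- st$pa_v[st$pa_n]
  exts <- vector("list", n)
  for (w in seq_len(n)) exts[[w]] <- ext_range(env, st, w, b)

  # candidate targets: vertices on extensions of walks ending at w0,
  # reachable without passing through a vertex already on the path
  cand_v <- integer(0); cand_len <- numeric(0); cand_w <- integer(0); cand_j <- integer(0)
  for (w in seq_len(n)) {
    if (st$W_endv[w] != w0) next
    rng <- exts[[w]]
    if (length(rng) == 0L) next
    o <- st$W_o[w]
    ids <- env$oe[[o]][rng]
    vs <- env$e_v[ids]
    seen <- env$vis_ser[vs] == env$ser_v
    cut <- if (any(seen)) which(seen)[1L] - 1L else length(vs)
    if (cut == 0L) next
    ocum <- env$oc[[o]]
    plen <- ocum[rng[seq_len(cut)] + 1L] - ocum[rng[1L]]
    cand_v <- c(cand_v, vs[seq_len(cut)])
    cand_len <- c(cand_len, plen)
    cand_w <- c(cand_w, rep.int(w, cut))
    cand_j <- c(cand_j, seq_len(cut))
  }
  if (length(cand_v) == 0L) return(NULL)

  uv <- sort(unique(cand_v))
  votes <- integer(length(uv))
  for (w in seq_len(n)) {
    rng <- exts[[w]]
    if (length(rng) == 0L) next
    vw <- unique(env$e_v[env$oe[[st$W_o[w]]][rng]])
    mi <- match(vw, uv)
    mi <- mi[!is.na(mi)]
    votes[mi] <- votes[mi] + 1L
  }
  rlen <- vapply(uv, function(v) min(cand_len[cand_v == v]), numeric(1))
  km <- env$cg$vertices[uv]
  rck <- ifelse(is.na(env$cg$rc_vid[uv]), km, env$cg$vertices[env$cg$rc_vid[uv]])
  canon <- ifelse(km <= rck, km, rck)
  pick <- order(-votes, rlen, canon, km, method = "radix")[1L]
  tv <- uv[pick]

  hit <- which(cand_v == tv & cand_len == rlen[pick])
  hit <- hit[order(cand_w[hit])][1L]
  w <- cand_w[hit]
  rng <- exts[[w]][seq_len(cand_j[hit])]
  env$oe[[st$W_o[w]]][rng]   # eids of r
}

take_snapshot <- function(st, score) {
  st$snap <- list(score = score, nW = st$nW,
                  i2 = st$W_i2[seq_len(st$nW)], pa_n = st$pa_n)
}

restore_snapshot <- function(env, st) {
  sn <- st$snap
  # drop walks created after the snapshot
  if (st$nW > sn$nW) {
    for (w in (sn$nW + 1L):st$nW) {
      unclaim_edges(env, env$oe[[st$W_o[w]]][st$W_i1[w]:st$W_i2[w]])
    }
    st$nW <- sn$nW
  }
  # truncate extended walks
  for (w in seq_len(st$nW)) {
    if (st$W_i2[w] > sn$i2[w]) {
      unclaim_edges(env, env$oe[[st$W_o[w]]][(sn$i2[w] + 1L):st$W_i2[w]])
      st$W_i2[w] <- sn$i2[w]
    }
  }
  # truncate the carrying path and re-mark visited vertices
  st$pa_n <- sn$pa_n
  env$ser_v <- env$ser_v + 1L
  vs <- st$pa_v[seq_len(st$pa_n)]
  env$vis_ser[vs] <- env$ser_v
  env$vis_idx[vs] <- seq_len(st$pa_n)
  for (w in seq_len(st$nW)) walk_replay(env, st, w)
  invisible(NULL)
}

# Mirror the whole state for the symmetric leftward extension.
reverse_state <- function(env, st) {
  n <- st$pa_n
  CN <- st$pa_cum[n]
  old_v <- st$pa_v[seq_len(n)]; old_cum <- st$pa_cum[seq_len(n)]
  st$pa_v[seq_len(n)] <- env$cg$rc_vid[rev(old_v)]
  st$pa_cum[seq_len(n)] <- CN - rev(old_cum)
  st$pa_lab[seq_len(n - 1L)] <- revcomp(rev(st$pa_lab[seq_len(n - 1L)]))
  env$ser_v <- env$ser_v + 1L
  vs <- st$pa_v[seq_len(n)]
  env$vis_ser[vs] <- env$ser_v
  env$vis_idx[vs] <- seq_len(n)
  for (w in seq_len(st$nW)) {
    o <- st$W_o[w]
    ids <- env$oe[[o]][st$W_i1[w]:st$W_i2[w]]
    tw <- env$e_twin[ids]
    o2 <- env$e_oseq[tw[1L]]
    st$W_o[w] <- o2
    st$W_i1[w] <- env$e_idx[tw[length(tw)]]
    st$W_i2[w] <- env$e_idx[tw[1L]]
    walk_replay(env, st, w)
  }
  invisible(NULL)
}

run_phases <- function(env, st, m, b) {
  sc <- score_walks(st, m, b)
  f <- if (length(sc)) sum(sc) else 0
  if (is.null(st$snap) || f > st$snap$score) take_snapshot(st, f)
  while (f >= 0) {
    r <- choose_extension(env, st, b)
    if (is.null(r)) break
    for (e in r) {
      pa_append(env, st, env$e_v[e], env$e_len[e], env$e_sp[e])
      update_walks(env, st, env$e_v[e])
      sc <- score_walks(st, m, b)
      f <- sum(sc)
      if (f > st$snap$score) take_snapshot(st, f)
    }
  }
  invisible(NULL)
}

# Carrying path of the current state as a vertex_walk.
pa_vertex_walk <- function(env, st) {
  n <- st$pa_n
  vertex_walk(env$cg$vertices[st$pa_v[seq_len(n)]],
              diff(st$pa_cum[seq_len(n)]), st$pa_lab[seq_len(n - 1L)])
}

walk_as_vertex_walk <- function(env, st, w) {
  ids <- env$oe[[st$W_o[w]]][st$W_i1[w]:st$W_i2[w]]
  vw <- vertex_walk(env$cg$vertices[c(env$e_u[ids[1L]], env$e_v[ids])],
                    env$e_len[ids], env$e_sp[ids])
  attr(vw, "occurrence") <- c(oseq = st$W_o[w], from = st$W_i1[w], to = st$W_i2[w])
  vw
}

# Explore one seed class; returns NULL or the candidate block (without
# touching the used marks).
explore_seed <- function(env, key, m, b) {
  eids <- env$cg$class_eids[[key]]
  for (x in eids) touch_range(env, env$e_oseq[x], env$e_idx[x], env$e_idx[x])
  occs <- eids[!env$used[eids] & env$e_dir[eids]]
  if (length(occs) == 0L) return(NULL)
  # palindromic spelled sequences: both twins qualify; keep one per pair
  tw <- env$e_twin[occs]
  dup <- !is.na(tw) & tw %in% occs & env$e_rank[occs] > env$e_rank[pmax(tw, 1L)]
  occs <- occs[!dup]
  u <- env$e_u[occs[1L]]; v <- env$e_v[occs[1L]]
  if (u == v) return(NULL)   # the carrying path must be a simple path
  occs <- occs[order(env$e_rank[occs])]

  env$ser_c <- env$ser_c + 1L
  env$ser_v <- env$ser_v + 1L
  st <- seed_state(env)
  st$b <- b
  pa_append(env, st, u, 0)
  pa_append(env, st, v, env$e_len[occs[1L]], env$e_sp[occs[1L]])
  for (x in occs) walk_create(env, st, x)

  run_phases(env, st, m, b)
  restore_snapshot(env, st)
  if (env$cg$comprehensive && st$snap$score > -Inf) {
    reverse_state(env, st)
    sc <- score_walks(st, m, b)
    take_snapshot(st, sum(sc))
    run_phases(env, st, m, b)
    restore_snapshot(env, st)
  }

  if (st$nW == 0L) return(NULL)
  keep <- which(st$W_len[seq_len(st$nW)] >= m)
  if (length(keep) < 2L) return(NULL)
  # authoritative rescoring with the exact chain decomposition
  pa <- pa_vertex_walk(env, st)
  walks <- lapply(keep, function(w) walk_as_vertex_walk(env, st, w))
  splits <- lapply(walks, function(p) decompose_chain(pa, p, b))
  lens <- vapply(walks, walk_length, numeric(1))
  scores <- vapply(seq_along(walks), function(i) {
    d <- splits[[i]]
    if (d$q1_len > b || d$q3_len > b) return(-Inf)
    lens[i] - (d$q1_len + d$q3_len)^2
  }, numeric(1))
  total <- sum(scores)
  if (!(total > 0)) return(NULL)
  occ_eids <- unlist(lapply(keep, function(w) env$oe[[st$W_o[w]]][st$W_i1[w]:st$W_i2[w]]))
  list(score = total,
       carrying_path = pa,
       walks = data.frame(oseq = st$W_o[keep], from = st$W_i1[keep],
                          to = st$W_i2[keep], length = lens, score = scores),
       walk_vws = walks,
       eids = occ_eids)
}

mark_used <- function(env, eids) {
  env$used[eids] <- TRUE
  tw <- env$e_twin[eids]
  tw <- tw[!is.na(tw)]
  if (length(tw)) env$used[tw] <- TRUE
  invisible(NULL)
}

# ---- public API ------------------------------------------------------------

#' Seed classes of a compacted graph
#'
#' Distinct compacted-edge classes in canonical lexicographic order (the
#' order in which the block finder tries them as seeds), skipping classes
#' whose occurrences are all used.
#'
#' @param cg a `cdbg`.
#' @param used optional used-edge store from [new_used()].
#' @return data.frame with `key`, endpoint k-mers `u` and `v`, `len`
#'   (underlying edges) and `n_occ` (unused occurrences).
#' @export
seed_classes <- function(cg, used = NULL) {
  used <- used %||% logical(nrow(cg$edges))
  rows <- lapply(cg$class_keys, function(key) {
    eids <- cg$class_eids[[key]]
    live <- eids[!used[eids]]
    if (length(live) == 0L) return(NULL)
    rep_e <- live[cg$edges$dir[live]][1L]
    if (is.na(rep_e)) rep_e <- live[1L]
    data.frame(key = key, u = cg$vertices[cg$edges$u[rep_e]],
               v = cg$vertices[cg$edges$v[rep_e]],
               len = cg$edges$len[rep_e], n_occ = length(live),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(key = character(0), u = character(0),
                                      v = character(0), len = numeric(0),
                                      n_occ = integer(0))
  rownames(out) <- NULL
  out
}

#' Grow one collinear block from a seed class
#'
#' Runs the seed-and-extend procedure for a single seed and returns the
#' best-scoring block it induces, without marking any edges used.
#'
#' @param cg a `cdbg`.
#' @param seed canonical class key (see [seed_classes()]).
#' @param b maximum bubble side length in underlying edges.
#' @param m minimum walk length in underlying edges.
#' @param used optional used-edge store.
#' @return `NULL`, or a list with the block `score`, the
#'   `carrying_path` ([vertex_walk()]), a `walks` table and the edge
#'   occurrence ids of the block.
#' @export
find_block_from_seed <- function(cg, seed, b, m, used = NULL) {
  if (!seed %in% cg$class_keys) stop_param("unknown seed class: ", seed)
  env <- lcb_engine(cg, used)
  explore_seed(env, seed, m, b)
}

#' Find all collinear blocks of a compacted graph
#'
#' Tries every compacted-edge class as a seed in canonical order,
#' accepts each induced block whose collinearity score is positive and
#' which has at least two walks of length at least `m`, and marks the
#' edges of accepted blocks (and their reverse-complement twins) as
#' used. Seeds may be explored speculatively in batches; an arbiter
#' replays any seed whose exploration could have seen marks written
#' earlier in its batch, so the result is identical to the serial run
#' for every batch size.
#'
#' @param cg a `cdbg` (comprehensive for double-stranded inputs).
#' @param b maximum bubble side length in underlying edges.
#' @param m minimum block (walk) length in underlying edges.
#' @param batch_size number of seeds explored per batch (1 = serial).
#' @return object of class `lcb_result`: list with `blocks` (engine
#'   blocks), `records` (a [block_set()] of trimmed, non-overlapping
#'   occurrences) and the parameters.
#' @export
find_collinear_blocks <- function(cg, b = 200, m = 50, batch_size = 1L) {
  if (b < 1 || m < 1) stop_param("b and m must be >= 1")
  env <- lcb_engine(cg)
  keys <- cg$class_keys
  blocks <- list()
  i <- 1L
  while (i <= length(keys)) {
    batch <- keys[seq(i, min(i + batch_size - 1L, length(keys)))]
    if (length(batch) == 1L) {
      res <- explore_seed(env, batch, m, b)
      if (!is.null(res)) {
        mark_used(env, res$eids)
        blocks[[length(blocks) + 1L]] <- res
      }
    } else {
      cand <- vector("list", length(batch))
      touched <- vector("list", length(batch))
      for (j in seq_along(batch)) {
        env$tmin[] <- Inf; env$tmax[] <- -Inf
        cand[j] <- list(explore_seed(env, batch[j], m, b))
        touched[[j]] <- cbind(env$tmin, env$tmax)
      }
      applied <- integer(0)
      for (j in seq_along(batch)) {
        conflict <- FALSE
        if (length(applied)) {
          ao <- env$e_oseq[applied]; ai <- env$e_idx[applied]
          conflict <- any(ai >= touched[[j]][ao, 1L] & ai <= touched[[j]][ao, 2L])
        }
        res <- if (conflict) explore_seed(env, batch[j], m, b) else cand[[j]]
        if (!is.null(res)) {
          mark_used(env, res$eids)
          tw <- env$e_twin[res$eids]
          applied <- c(applied, res$eids, tw[!is.na(tw)])
          blocks[[length(blocks) + 1L]] <- res
        }
      }
    }
    i <- i + length(batch)
  }
  records <- blocks_to_records(cg, blocks)
  out <- list(blocks = records$blocks, records = records$records,
              params = list(k = cg$k, b = b, m = m, batch_size = batch_size))
  class(out) <- "lcb_result"
  out
}

#' @export
print.lcb_result <- function(x, ...) {
  cat(sprintf("collinear blocks: %d block(s), %d occurrence(s) (k=%d, b=%g, m=%g)\n",
              length(unique(x$records$block_id)), nrow(x$records),
              x$params$k, x$params$b, x$params$m))
  invisible(x)
}

# Convert engine blocks to genomic block records. Occurrence intervals of
# adjacent blocks can share up to k flanking bases (walks of edge-disjoint
# blocks may share junction k-mers); a deterministic sweep trims the
# later-starting occurrence so the reported records never overlap.
blocks_to_records <- function(cg, blocks) {
  if (length(blocks) == 0L) {
    rec <- data.frame(block_id = integer(0), genome_id = character(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    class(rec) <- c("block_set", "data.frame")
    return(list(blocks = blocks, records = rec))
  }
  occ <- do.call(rbind, lapply(seq_along(blocks), function(bi) {
    w <- blocks[[bi]]$walks
    iv <- t(vapply(seq_len(nrow(w)), function(r)
      walk_interval(cg, w$oseq[r], w$from[r], w$to[r]), numeric(2)))
    ci <- cg$oseq$contig_idx[w$oseq]
    data.frame(block_id = bi, contig_idx = ci,
               genome_id = cg$contigs$genome_id[ci],
               seq_id = cg$contigs$seq_id[ci],
               start = iv[, 1L], end = iv[, 2L],
               strand = cg$oseq$strand[w$oseq], stringsAsFactors = FALSE)
  }))
  # Trim overlaps (at most k bases at shared junctions) per contig.
  # Earlier-accepted blocks keep their bases; the trimming order is
  # position-free so mirrored inputs give mirrored records.
  occ <- occ[order(occ$block_id, -(occ$end - occ$start), occ$genome_id,
                   occ$seq_id, occ$start), , drop = FALSE]
  drop <- logical(nrow(occ))
  for (ci in unique(occ$contig_idx)) {
    rows <- which(occ$contig_idx == ci)
    kept_s <- integer(0); kept_e <- integer(0)
    for (r in rows) {
      s <- occ$start[r]; e <- occ$end[r]
      ov <- which(kept_s < e & kept_e > s)
      for (kx in ov) {
        if (kept_s[kx] <= s) s <- max(s, kept_e[kx])
        else if (kept_e[kx] >= e) e <- min(e, kept_s[kx])
      }
      if (e - s <= 0L) { drop[r] <- TRUE; next }
      occ$start[r] <- s; occ$end[r] <- e
      kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
    }
  }
  occ <- occ[!drop & occ$end - occ$start > 0L, , drop = FALSE]
  cnt <- table(occ$block_id)
  keep_b <- as.integer(names(cnt)[cnt >= 2L])
  occ <- occ[occ$block_id %in% keep_b, , drop = FALSE]
  blocks <- blocks[keep_b]
  occ$block_id <- match(occ$block_id, keep_b)
  rec <- block_set(occ$block_id, occ$genome_id, occ$seq_id, occ$start,
                   occ$end, occ$strand)
  list(blocks = blocks, records = rec)
}
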