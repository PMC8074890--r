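# Independent oracles used against the package implementation.

# neighbor offsets covering the positive half-space (each undirected pair once)
half_offsets <- function(connectivity) {
  full <- connectivity %in% c(8L, 26L)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (!full) offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  # keep one direction per pair (lexicographically positive)
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, , drop = FALSE])
}

# connected components of the solid phase via igraph - an implementation
# path fully independent of the package's BFS labeling
oracle_components <- function(mask, connectivity) {
  d <- dim(mask)
  if (length(d) == 2L) { d <- c(d, 1L); dim(mask) <- d }
  solid <- which(mask == 1L)
  if (length(solid) == 0L) return(array(0L, d))
  idx <- array(0L, d)
  idx[solid] <- seq_along(solid)
  co <- arrayInd(solid, d)
  edges <- list()
  for (r in seq_len(nrow(half_offsets(connectivity)))) {
    off <- half_offsets(connectivity)[r, ]
    nb <- sweep(co, 2L, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    to <- idx[nb[ok, , drop = FALSE]]
    from <- idx[co[ok, , drop = FALSE]]
    hit <- to > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(from[hit], to[hit])
  }
  g <- igraph::make_empty_graph(n = length(solid), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[solid] <- as.integer(memb)
  lab
}

# flood-fill-and-threshold re-implementation of the cluster filter
oracle_trim <- function(mask, min_size, connectivity) {
  lab <- oracle_components(mask, connectivity)
  dim(lab) <- dim(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  out <- mask
  out[array(lab %in% which(sizes < min_size), dim(mask))] <- 0L
  out
}

random_mask <- function(dims, p_solid = 0.3) {
  array(as.integer(stats::runif(prod(dims)) < p_solid), dim = dims)
}

# greedy representative selection re-implemented from scratch (no shared code)
oracle_select <- function(m, threshold) {
  if (is.null(rownames(m))) rownames(m) <- paste0("model", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sample", seq_len(ncol(m)))
  remaining <- colnames(m)
  picks <- list()
  repeat {
    cover <- lapply(rownames(m), function(i)
      remaining[m[i, remaining] < threshold])
    names(cover) <- rownames(m)
    ncov <- vapply(cover, length, 0L)
    if (!length(remaining) || max(ncov) == 0L) break
    cand <- names(ncov)[ncov == max(ncov)]
    if (length(cand) > 1L) {
      me <- vapply(cand, function(i) mean(m[i, cover[[i]]]), 0)
      cand <- cand[me == min(me)]
      cand <- sort(cand)[1]
    }
    pick <- cand[1]
    picks[[pick]] <- cover[[pick]]
    remaining <- setdiff(remaining, cover[[pick]])
  }
  list(covered = picks, uncovered = remaining)
}
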