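# Independent oracles, deliberately naive: brute-force double loops,
# flood fill, exhaustive permutation. They never share code with the
# implementation paths they check.

# O(n^2) all-pairs oracle for fixed-radius cross-type pairing.
bf_pairs <- function(anchors, partners, radius_um) {
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(partners))) {
      if (anchors$id[i] == partners$id[j]) next
      d <- sqrt((anchors$x_um[i] - partners$x_um[j])^2 +
                (anchors$y_um[i] - partners$y_um[j])^2)
      if (d <= radius_um) {
        out[[length(out) + 1L]] <- data.frame(
          anchor_id = anchors$id[i], partner_id = partners$id[j],
          distance_um = d)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(anchor_id = integer(0), partner_id = integer(0),
                      distance_um = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$anchor_id, res$partner_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# BFS flood-fill connected-component labelling (independent of igraph).
floodfill_components <- function(grid, connectivity = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  comp <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!grid[r, cc] || lab[r, cc] != 0L) next
    comp <- comp + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- comp
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r2 <- cur[1] + nbr[k, 1]; c2 <- cur[2] + nbr[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            grid[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- comp
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  list(n = comp, labels = lab)
}

# Exhaustive-permutation two-tailed Mann-Whitney p: over all C(nx+ny, nx)
# assignments of the pooled values to group x, the fraction with a U at
# least as extreme (distance from nx*ny/2) as observed.
mw_perm_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  centre <- nx * ny / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# Direct midrank Spearman rho and its t-approximation p.
spearman_direct <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}
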