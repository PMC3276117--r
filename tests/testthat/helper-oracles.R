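# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementation.

# all unordered ICN pairs by exhaustive double loop
oracle_icn_pairs <- function(total, cap) {
  out <- character(0)
  for (a in 0:total) for (b in 0:total) {
    if (a + b == total && a <= cap && b <= cap) {
      out <- c(out, paste(sort(c(a, b)), collapse = "/"))
    }
  }
  sort(unique(out))
}

# all unordered bipartitions of a base multiset: assign each unit to part 1
# or part 2, serialize, deduplicate
oracle_snvc_pairs <- function(units, cap, alphabet) {
  ser <- function(u) if (!length(u)) "-" else
    paste(u[order(match(u, alphabet))], collapse = ",")
  n <- length(units)
  out <- character(0)
  for (mask in 0:(2^n - 1)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    p1 <- units[take]
    p2 <- units[!take]
    if (length(p1) > cap || length(p2) > cap) next
    out <- c(out, paste(sort(c(ser(p1), ser(p2))), collapse = "/"))
  }
  sort(unique(out))
}

# multi-site expansion by exhaustive orientation enumeration
oracle_multisite <- function(per_site) {
  combos <- expand.grid(lapply(per_site, function(m) seq_len(nrow(m))))
  out <- character(0)
  n_sites <- length(per_site)
  for (r in seq_len(nrow(combos))) {
    for (mask in 0:(2^n_sites - 1)) {
      flip <- as.logical(bitwAnd(mask, 2^(seq_len(n_sites) - 1)))
      h1 <- h2 <- character(n_sites)
      for (s in seq_len(n_sites)) {
        row <- per_site[[s]][combos[r, s], ]
        h1[s] <- if (flip[s]) row[2] else row[1]
        h2[s] <- if (flip[s]) row[1] else row[2]
      }
      a <- paste(h1, collapse = "_")
      b <- paste(h2, collapse = "_")
      out <- c(out, paste(sort(c(a, b)), collapse = "/"))
    }
  }
  sort(unique(out))
}

# classic deterministic EM (hard calls, lambda = 1) written independently:
# plain loops over individuals, no shared code with run_em
oracle_classic_em <- function(dip_list, n_iter = 2000, tol = 1e-10) {
  haps <- sort(unique(unlist(dip_list)))
  p <- setNames(rep(1 / length(haps), length(haps)), haps)
  n <- length(dip_list)
  for (it in seq_len(n_iter)) {
    cnt <- setNames(rep(0, length(haps)), haps)
    for (j in seq_len(n)) {
      dips <- dip_list[[j]]  # matrix: rows = (h1, h2)
      pr <- numeric(nrow(dips))
      for (k in seq_len(nrow(dips))) {
        pr[k] <- p[dips[k, 1]] * p[dips[k, 2]] *
          (if (dips[k, 1] == dips[k, 2]) 1 else 2)
      }
      w <- pr / sum(pr)
      for (k in seq_len(nrow(dips))) {
        cnt[dips[k, 1]] <- cnt[dips[k, 1]] + w[k]
        cnt[dips[k, 2]] <- cnt[dips[k, 2]] + w[k]
      }
    }
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p
}

# direct maximization of the mixture log-likelihood over a grid of the
# 3-haplotype frequency simplex
oracle_grid_max <- function(expansion_table, haps, step = 1e-3) {
  stopifnot(length(haps) == 3)
  g <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = g, p2 = g)
  grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
  p1 <- grid$p1; p2 <- grid$p2; p3 <- pmax(0, 1 - p1 - p2)
  ll <- 0
  for (j in unique(expansion_table$ind)) {
    sub <- expansion_table[expansion_table$ind == j, ]
    inner <- 0
    for (k in seq_len(nrow(sub))) {
      i1 <- match(sub$h1[k], haps)
      i2 <- match(sub$h2[k], haps)
      pa <- list(p1, p2, p3)[[i1]]
      pb <- list(p1, p2, p3)[[i2]]
      inner <- inner + sub$lambda[k] * pa * pb * (if (i1 == i2) 1 else 2)
    }
    ll <- ll + log(inner)
  }
  best <- which.max(ll)
  c(p1[best], p2[best], p3[best])
}

# tiny deterministic spectrum builders for fixtures
point_mass_spectrum <- function(ids, site_id, states) {
  geno_spectrum(ids, site_id, states, rep(1, length(ids)))
}
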