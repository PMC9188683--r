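# Brute-force reference implementations of the texture matrices, written
# directly from the definitions with explicit loops. They are
# deliberately slow and independent of the package's compiled path; the
# unit tests treat them as the source of truth on small windows.

oracle_glcm <- function(q, L) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  m <- matrix(0, L, L)
  for (d in dirs) {
    for (r in seq_len(nrow(q))) {
      for (cc in seq_len(ncol(q))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr < 1 || rr > nrow(q) || c2 < 1 || c2 > ncol(q)) next
        a <- q[r, cc]; b <- q[rr, c2]
        m[a, b] <- m[a, b] + 1
        m[b, a] <- m[b, a] + 1
      }
    }
  }
  m / sum(m)
}

# all maximal runs of one direction, as (level, length) rows
oracle_runs_dir <- function(q, d) {
  H <- nrow(q); W <- ncol(q)
  runs <- NULL
  inb <- function(r, cc) r >= 1 && r <= H && cc >= 1 && cc <= W
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      # start of a line: predecessor out of bounds
      if (inb(r0 - d[1], c0 - d[2])) next
      line <- c()
      r <- r0; cc <- c0
      while (inb(r, cc)) {
        line <- c(line, q[r, cc])
        r <- r + d[1]; cc <- cc + d[2]
      }
      rl <- rle(line)
      runs <- rbind(runs, cbind(rl$values, rl$lengths))
    }
  }
  runs
}

oracle_glrlm <- function(q, L) {
  dirs <- list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  runs <- do.call(rbind, lapply(dirs, function(d) oracle_runs_dir(q, d)))
  m <- matrix(0, L, max(nrow(q), ncol(q)))
  for (i in seq_len(nrow(runs))) {
    m[runs[i, 1], runs[i, 2]] <- m[runs[i, 1], runs[i, 2]] + 1
  }
  m
}

# 8-connected zones by repeated flood fill over a logical mask
oracle_zones <- function(q) {
  H <- nrow(q); W <- ncol(q)
  seen <- matrix(FALSE, H, W)
  zones <- NULL
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      if (seen[r0, c0]) next
      lev <- q[r0, c0]
      frontier <- matrix(c(r0, c0), 1)
      seen[r0, c0] <- TRUE
      size <- 0
      while (nrow(frontier) > 0) {
        nxt <- NULL
        for (i in seq_len(nrow(frontier))) {
          size <- size + 1
          for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            r <- frontier[i, 1] + dr; cc <- frontier[i, 2] + dc
            if (r < 1 || r > H || cc < 1 || cc > W) next
            if (seen[r, cc] || q[r, cc] != lev) next
            seen[r, cc] <- TRUE
            nxt <- rbind(nxt, c(r, cc))
          }
        }
        frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
      }
      zones <- rbind(zones, c(lev, size))
    }
  }
  zones
}

oracle_glszm_counts <- function(q, L) {
  z <- oracle_zones(q)
  m <- matrix(0, L, max(z[, 2]))
  for (i in seq_len(nrow(z))) {
    m[z[i, 1], z[i, 2]] <- m[z[i, 1], z[i, 2]] + 1
  }
  m
}

oracle_ngtdm <- function(q, L) {
  n_i <- numeric(L); s_i <- numeric(L)
  for (r in 2:(nrow(q) - 1)) {
    for (cc in 2:(ncol(q) - 1)) {
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nb <- c(nb, q[r + dr, cc + dc])
      }
      i <- q[r, cc]
      n_i[i] <- n_i[i] + 1
      s_i[i] <- s_i[i] + abs(i - mean(nb))
    }
  }
  cbind(n_i, s_i)
}

# gl_matrix_stats re-derived longhand from the definitions
oracle_gl_stats <- function(counts, n_pixels, n_dir) {
  nr <- sum(counts)
  vals <- NULL
  for (g in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      if (counts[g, s] > 0) {
        vals <- rbind(vals, c(g = g, s = s, n = counts[g, s]))
      }
    }
  }
  p <- vals[, "n"] / nr
  g <- vals[, "g"]; s <- vals[, "s"]
  mu_g <- sum(g * p); mu_s <- sum(s * p)
  c(sum(p / s^2), sum(p * s^2),
    sum(tapply(vals[, "n"], g, sum)^2) / nr,
    sum(tapply(vals[, "n"], s, sum)^2) / nr,
    nr / (n_dir * n_pixels),
    sum(p / g^2), sum(p * g^2),
    sum(p / (g^2 * s^2)), sum(p * g^2 / s^2),
    sum(p * s^2 / g^2), sum(p * g^2 * s^2),
    sum((g - mu_g)^2 * p), sum((s - mu_s)^2 * p))
}
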