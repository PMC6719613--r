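# Independent brute-force oracles used to validate the package's texture,
# ROC and survival computations. These deliberately share no code with the
# implementation: zones come from union-find, runs from explicit line
# walks, AUC from trapezoidal ROC integration, the log-rank statistic from
# the hypergeometric table, and the Cox fit from a hand-rolled Newton
# iteration on the partial likelihood.

make_disc <- function(levels, G = max(levels)) {
  structure(list(levels = array(as.integer(levels), dim = dim(levels)),
                 n_levels = as.integer(G),
                 scheme = discretization_scheme("fixed-bin-number",
                                                max(2, G))),
            class = "discretized_roi")
}

# Zone enumeration by union-find.
oracle_zones <- function(lev, connectivity = 26) {
  dm <- dim(lev)
  n <- prod(dm)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  coord <- arrayInd(seq_len(n), dm)
  for (i in seq_len(n)) {
    if (lev[i] == 0) next
    for (k in seq_len(nrow(offs))) {
      nb <- coord[i, ] + c(offs$dx[k], offs$dy[k], offs$dz[k])
      if (any(nb < 1) || any(nb > dm)) next
      j <- nb[1] + dm[1] * (nb[2] - 1) + dm[1] * dm[2] * (nb[3] - 1)
      if (lev[j] == lev[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(which(lev != 0), function(i) as.integer(find(i)),
                  integer(1))
  sizes <- table(roots)
  data.frame(level = as.integer(lev[as.integer(names(sizes))]),
             size = as.integer(sizes))
}

# Tabulate a zone list into a GLSZM count matrix.
oracle_glszm <- function(lev, connectivity = 26, G = max(lev)) {
  z <- oracle_zones(lev, connectivity)
  jmax <- max(z$size)
  m <- matrix(0, G, jmax)
  for (k in seq_len(nrow(z))) m[z$level[k], z$size[k]] <-
      m[z$level[k], z$size[k]] + 1
  m
}

# The 13 unique directions, declared independently.
ORACLE_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                     c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                     c(0, 1, 1), c(0, 1, -1),
                     c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# Per-direction run matrices by explicit line walking.
oracle_glrlm_per_direction <- function(lev, G = max(lev)) {
  dm <- dim(lev)
  jcap <- max(dm)
  out <- list()
  for (d in seq_len(nrow(ORACLE_DIRS))) {
    dir <- ORACLE_DIRS[d, ]
    m <- matrix(0, G, jcap)
    coords <- arrayInd(seq_len(prod(dm)), dm)
    for (i in seq_len(nrow(coords))) {
      prev <- coords[i, ] - dir
      if (all(prev >= 1) && all(prev <= dm)) next  # line continues backwards
      # walk the full line, splitting into runs
      pos <- coords[i, ]
      run_level <- 0L; run_len <- 0L
      while (all(pos >= 1) && all(pos <= dm)) {
        g <- lev[pos[1], pos[2], pos[3]]
        if (g == run_level && g != 0L) {
          run_len <- run_len + 1L
        } else {
          if (run_level != 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
          run_level <- g; run_len <- 1L
        }
        pos <- pos + dir
      }
      if (run_level != 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
    }
    out[[d]] <- m
  }
  out
}

oracle_glrlm <- function(lev, G = max(lev)) {
  Reduce(`+`, oracle_glrlm_per_direction(lev, G))
}

# Double-loop feature evaluations on raw count matrices.
oracle_sze <- function(m) {
  tot <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    tot <- tot + m[i, j] / j^2
  tot / sum(m)
}
oracle_szlge <- function(m) {
  tot <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    tot <- tot + m[i, j] / (i^2 * j^2)
  tot / sum(m)
}
oracle_hgre <- function(m) {
  tot <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    tot <- tot + i^2 * m[i, j]
  tot / sum(m)
}

# Mirror-extended 1-D correlation with explicit loops (wavelet oracle).
oracle_filter_1d <- function(x, f, center = 3L) {
  n <- length(x)
  ext <- function(p) {
    q <- ((p - 1) %% (2 * n) + 2 * n) %% (2 * n)
    if (q < n) x[q + 1] else x[2 * n - q]
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(f)) acc <- acc + f[t] * ext(i + t - center)
    out[i] <- acc
  }
  out
}

oracle_filter_volume <- function(a, fs, center = 3L) {
  dm <- dim(a)
  out <- a
  for (y in seq_len(dm[2])) for (z in seq_len(dm[3]))
    out[, y, z] <- oracle_filter_1d(out[, y, z], fs[[1]], center)
  for (x in seq_len(dm[1])) for (z in seq_len(dm[3]))
    out[x, , z] <- oracle_filter_1d(out[x, , z], fs[[2]], center)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    out[x, y, ] <- oracle_filter_1d(out[x, y, ], fs[[3]], center)
  out
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_trapz_auc <- function(values, labels) {
  ths <- c(-Inf, sort(unique(values)), Inf)
  se <- sp <- numeric(length(ths))
  for (k in seq_along(ths)) {
    pred <- values >= ths[k]
    se[k] <- sum(pred & labels == 1) / sum(labels == 1)
    sp[k] <- sum(!pred & labels == 0) / sum(labels == 0)
  }
  fpr <- 1 - sp
  ord <- order(fpr, se)
  fpr <- fpr[ord]; tpr <- se[ord]
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Log-rank statistic from the hypergeometric table (group = first level).
oracle_logrank_chisq <- function(groups, times, events) {
  g <- as.integer(factor(groups)) == 1L
  u <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# One-covariate Cox partial likelihood by Newton iteration (Breslow ties;
# used on fixtures with distinct event times, where tie handling is moot).
oracle_cox_beta <- function(x, times, events) {
  beta <- 0
  for (it in 1:50) {
    u <- 0; info <- 0
    for (t in times[events == 1]) {
      rs <- which(times >= t)
      w <- exp(beta * x[rs])
      xb <- sum(w * x[rs]) / sum(w)
      x2 <- sum(w * x[rs]^2) / sum(w)
      i_ev <- which(times == t & events == 1)
      u <- u + sum(x[i_ev]) - length(i_ev) * xb
      info <- info + length(i_ev) * (x2 - xb^2)
    }
    step <- u / info
    beta <- beta + step
    if (abs(step) < 1e-12) break
  }
  beta
}

# Small helper: deterministic random discretized ROI.
random_disc <- function(size, G, seed, p_roi = 0.8) {
  set.seed(seed)
  lev <- array(0L, dim = rep(size, 3))
  roi <- array(runif(size^3) < p_roi, dim = rep(size, 3))
  lev[roi] <- sample.int(G, sum(roi), replace = TRUE)
  if (all(lev == 0)) lev[1] <- 1L
  make_disc(lev, G)
}
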